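#' Configure a synthetic blood-transcriptome cohort
#'
#' Builds the parameter set for [generate_cohort()]. The defaults emulate a
#' population blood-transcriptome cohort at desk scale: 13 planted gene
#' modules whose activations define three sample types (labelled `"1"`,
#' `"M"`, `"2"`) with anti-correlated extremes and an intermediate type,
#' each split into three subtypes realised as distinct combinations of
#' boosted modules, plus phenotype covariates (age, sex, BMI, a binary
#' disease flag) linearly coupled to module activations.
#'
#' The activation model for sample `s` and module `m` is
#' `a[s, m] = base[type(s), m] + boost * (m in boost_set(subtype(s))) +
#' sum_p beta[p, m] * phen[s, p]`, and gene expression is
#' `e[g, s] = a[s, module(g)] + noise` (background genes are pure noise).
#' One module (the last) is coupled to no type and activates in a random
#' fraction of samples across all types, emulating a type-independent
#' interferon-response module.
#'
#' @param n_genes Total number of genes.
#' @param n_samples Number of samples.
#' @param n_modules Number of planted co-expression modules (last one is
#'   type-independent when `n_modules > 2 * n_types`).
#' @param module_size Genes per module.
#' @param n_types Number of sample types.
#' @param n_subtypes_per_type Subtypes within each type.
#' @param activation_matrix Optional `n_types x n_modules` matrix of base
#'   activations (log2 units). Default: each extreme type's own module
#'   block +3, the opposite extreme's block -3; the intermediate type
#'   carries `mid_base` on the cross-pair module pool only.
#' @param subtype_boosts Optional named list mapping subtype label to the
#'   integer module indices boosted in that subtype.
#' @param boost Activation boost (log2 units) applied to an extreme-type
#'   subtype's modules.
#' @param mid_boost Activation boost for intermediate-type subtypes'
#'   cross-block module pairs (moderate: mixtures of both extremes'
#'   modules, emulating the heterogeneous middle stratum).
#' @param mid_base Base activation of the intermediate type on the
#'   cross-pair module pool, its own shared signature (the middle stratum
#'   is a distinguishable state, not the exact midpoint of the extremes).
#' @param phenotype_effects Tibble with columns `phenotype`, `module`,
#'   `beta`: linear couplings of phenotype values into module activations.
#' @param noise_sd Residual standard deviation (log2 units).
#' @param free_module_rate Fraction of samples in which the type-independent
#'   module is active.
#' @param seed Integer RNG seed; all randomness flows from it.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 2000,
                          n_samples = 300,
                          n_modules = 13,
                          module_size = 40,
                          n_types = 3,
                          n_subtypes_per_type = 3,
                          activation_matrix = NULL,
                          subtype_boosts = NULL,
                          boost = 5,
                          mid_boost = 3.5,
                          mid_base = 3,
                          phenotype_effects = default_phenotype_effects(),
                          noise_sd = 1.0,
                          free_module_rate = 0.10,
                          seed = 1L) {
  if (n_modules * module_size > n_genes) {
    stop("config error: n_modules * module_size (", n_modules * module_size,
         ") exceeds n_genes (", n_genes, ")", call. = FALSE)
  }
  if (n_types < 1 || n_subtypes_per_type < 1) {
    stop("config error: n_types and n_subtypes_per_type must be >= 1",
         call. = FALSE)
  }
  type_labels <- type_label_set(n_types)
  has_free <- is.null(activation_matrix) && n_modules > 2 * n_types
  if (is.null(activation_matrix)) {
    activation_matrix <- default_activation_matrix(n_types, n_modules,
                                                   has_free, mid_base)
  }
  activation_matrix <- as.matrix(activation_matrix)
  if (!all(dim(activation_matrix) == c(n_types, n_modules))) {
    stop("config error: activation_matrix must be n_types x n_modules",
         call. = FALSE)
  }
  rownames(activation_matrix) <- type_labels
  if (n_types >= 2) {
    r <- suppressWarnings(stats::cor(activation_matrix[1L, ],
                                     activation_matrix[n_types, ]))
    if (is.finite(r) && r >= 0) {
      stop("config error: extreme type rows of activation_matrix must be ",
           "anti-correlated over modules", call. = FALSE)
    }
  }
  if (is.null(subtype_boosts)) {
    subtype_boosts <- default_subtype_boosts(n_types, n_subtypes_per_type,
                                             n_modules, has_free)
  }
  if (any(unlist(subtype_boosts) > n_modules)) {
    stop("config error: subtype_boosts reference modules beyond n_modules",
         call. = FALSE)
  }
  structure(list(
    n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
    n_modules = as.integer(n_modules), module_size = as.integer(module_size),
    n_types = as.integer(n_types),
    n_subtypes_per_type = as.integer(n_subtypes_per_type),
    type_labels = type_labels,
    activation_matrix = activation_matrix,
    subtype_boosts = subtype_boosts,
    boost = boost,
    mid_boost = mid_boost,
    mid_base = mid_base,
    phenotype_effects = phenotype_effects,
    noise_sd = noise_sd,
    free_module = if (has_free) n_modules else NA_integer_,
    free_module_rate = free_module_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Extreme types first and last, intermediate types labelled "M" (or "M1",
# "M2", ... when more than one).
type_label_set <- function(n_types) {
  if (n_types == 1) return("1")
  if (n_types == 2) return(c("1", "2"))
  mids <- if (n_types == 3) "M" else paste0("M", seq_len(n_types - 2))
  c("1", mids, "2")
}

# The core modules split into two blocks owned by the extreme types: up
# (+3) in the owning type, down (-3) in the opposite extreme. Intermediate
# types own no modules (all-zero rows) — their identity comes from mixed
# subtype boosts, mirroring cohorts where the middle stratum shows
# combinations of both extremes' modules. The optional last module is free
# (all-zero row), activated i.i.d. across samples by generate_cohort().
extreme_blocks <- function(n_core) {
  half <- n_core %/% 2
  list(lo = seq_len(half), hi = seq.int(half + 1L, n_core))
}

default_activation_matrix <- function(n_types, n_modules, has_free,
                                      mid_base = 3) {
  n_core <- n_modules - as.integer(has_free)
  A <- matrix(0, n_types, n_modules)
  if (n_types == 1) {
    A[1, seq_len(n_core)] <- 3
    return(A)
  }
  b <- extreme_blocks(n_core)
  A[1L, b$lo] <- 3; A[1L, b$hi] <- -3
  A[n_types, b$hi] <- 3; A[n_types, b$lo] <- -3
  if (n_types > 2) {
    # intermediate types moderately activate the cross-pair module pool
    # (even positions of both blocks): a shared signature of their own,
    # off the type-1/type-2 axis, rather than sitting exactly midway
    pool <- c(b$lo[seq_along(b$lo) %% 2L == 0L],
              b$hi[seq_along(b$hi) %% 2L == 0L])
    for (t in seq.int(2L, n_types - 1L)) A[t, pool] <- mid_base
  }
  A
}

# Subtype j of an extreme type boosts a cyclic window of 3 modules from the
# type's own block (stride 2, so the windows jointly cover the block and
# every module gets a unique subtype signature); subtypes of intermediate
# types boost one module from each extreme block, so that mixed
# combinatorial patterns occur.
default_subtype_boosts <- function(n_types, n_sub, n_modules, has_free) {
  n_core <- n_modules - as.integer(has_free)
  labels <- type_label_set(n_types)
  blocks <- if (n_types == 1) {
    list(seq_len(n_core))
  } else {
    b <- extreme_blocks(n_core)
    c(list(b$lo), rep(list(integer(0)), n_types - 2L), list(b$hi))
  }
  out <- list()
  for (t in seq_len(n_types)) {
    B <- blocks[[t]]
    b <- length(B)
    for (j in seq_len(n_sub)) {
      key <- paste0(labels[t], ".", j)
      if (b > 0) {
        w <- min(3L, b)
        stride <- max(1L, b %/% n_sub)
        out[[key]] <- sort(B[((j - 1L) * stride + seq_len(w) - 1L) %% b + 1L])
      } else {
        lo <- blocks[[1L]]
        hi <- blocks[[n_types]]
        i1 <- ((2L * j - 1L) %% length(lo)) + 1L
        i2 <- ((2L * j - 1L) %% length(hi)) + 1L
        out[[key]] <- c(lo[i1], hi[i2])
      }
    }
  }
  out
}

#' Default phenotype-to-module couplings
#'
#' One coupled module per phenotype: age (per year), sex (0/1), BMI (per
#' kg/m^2) and a binary disease flag. Slopes are in log2-expression units
#' per phenotype unit.
#'
#' @return A tibble with columns `phenotype`, `module`, `beta`.
#' @export
default_phenotype_effects <- function() {
  tibble::tibble(
    phenotype = c("age", "sex", "bmi", "disease"),
    module = c(2L, 8L, 5L, 10L),
    beta = c(0.03, 1.0, 0.08, 1.5)
  )
}

#' Generate a synthetic cohort with planted structure
#'
#' Draws a genes x samples log2-expression matrix, a phenotype table and the
#' full ground truth (gene-to-module map, sample type/subtype labels,
#' realised module activations) from a [cohort_config()]. Deterministic
#' given the config's seed.
#'
#' Sample (type, subtype) labels are allocated as evenly as possible and
#' then shuffled. Phenotypes: age ~ Uniform(40, 80) years; sex ~
#' Bernoulli(0.5) coded 0/1; BMI ~ Normal(27, 4) with a mild age trend; the
#' disease flag follows a logistic threshold on age with an elevated rate in
#' type-1 samples (emulating a disease association of the inflammatory
#' type).
#'
#' @param config A [cohort_config()].
#' @return A list of class `som_cohort` with elements `expression` (matrix,
#'   genes x samples), `phenotypes` (tibble) and `truth` (list with
#'   `gene_module`, `sample_type`, `module_activation`, `phenotypes`,
#'   `config`).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_genes = 200, n_samples = 60,
#'                                         n_modules = 4, module_size = 10))
#' dim(cohort$expression)
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_s <- config$n_samples
  n_g <- config$n_genes
  n_m <- config$n_modules

  ## type / subtype labels, balanced then shuffled
  sub_labels <- names(config$subtype_boosts)
  alloc <- rep_len(sub_labels, n_s)
  alloc <- alloc[sample.int(n_s)]
  type_of <- sub("\\..*$", "", alloc)

  sample_ids <- sprintf("S%04d", seq_len(n_s))
  gene_ids <- sprintf("g%05d", seq_len(n_g))

  ## phenotypes
  age <- stats::runif(n_s, 40, 80)
  sex <- stats::rbinom(n_s, 1L, 0.5)
  bmi <- stats::rnorm(n_s, 27, 4) + 0.05 * (age - 60)
  p_dis <- stats::plogis(-2.5 + 2 * (type_of == "1") + 0.02 * (age - 60))
  disease <- stats::rbinom(n_s, 1L, p_dis)
  phenotypes <- tibble::tibble(sample_id = sample_ids, age = age,
                               sex = sex, bmi = bmi, disease = disease)

  ## realised activations: samples x modules
  A <- config$activation_matrix[type_of, , drop = FALSE]
  extreme_types <- config$type_labels[c(1L, config$n_types)]
  for (lab in sub_labels) {
    idx <- which(alloc == lab)
    amp <- if (sub("\\..*$", "", lab) %in% extreme_types) {
      config$boost
    } else {
      config$mid_boost
    }
    A[idx, config$subtype_boosts[[lab]]] <-
      A[idx, config$subtype_boosts[[lab]]] + amp
  }
  if (!is.na(config$free_module)) {
    active <- stats::runif(n_s) < config$free_module_rate
    A[, config$free_module] <- A[, config$free_module] +
      config$boost * active
  }
  pe <- config$phenotype_effects
  if (!is.null(pe) && nrow(pe)) {
    for (i in seq_len(nrow(pe))) {
      ph <- pe$phenotype[i]
      if (!ph %in% names(phenotypes) || pe$module[i] > n_m) next
      A[, pe$module[i]] <- A[, pe$module[i]] +
        pe$beta[i] * phenotypes[[ph]]
    }
  }
  dimnames(A) <- list(sample_ids, paste0("m", seq_len(n_m)))

  ## expression: module genes inherit their module's activation profile
  gene_module <- rep(NA_integer_, n_g)
  gene_module[seq_len(n_m * config$module_size)] <-
    rep(seq_len(n_m), each = config$module_size)
  E <- matrix(stats::rnorm(n_g * n_s, sd = config$noise_sd), n_g, n_s,
              dimnames = list(gene_ids, sample_ids))
  in_mod <- !is.na(gene_module)
  E[in_mod, ] <- E[in_mod, ] + t(A[, gene_module[in_mod], drop = FALSE])

  truth <- list(
    gene_module = tibble::tibble(gene_id = gene_ids, module = gene_module),
    sample_type = tibble::tibble(sample_id = sample_ids, type = type_of,
                                 subtype = alloc),
    module_activation = A,
    phenotypes = phenotypes,
    config = config
  )
  structure(list(expression = E, phenotypes = phenotypes, truth = truth),
            class = "som_cohort")
}

#' @export
print.som_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$expression), "genes x",
      ncol(x$expression), "samples;",
      x$truth$config$n_modules, "planted modules;",
      length(unique(x$truth$sample_type$type)), "types /",
      length(unique(x$truth$sample_type$subtype)), "subtypes\n")
  invisible(x)
}

#' Match detected spots to planted modules
#'
#' Greedy one-to-one matching of detected spot gene sets to planted module
#' gene sets by Jaccard index: the best-scoring (spot, module) pair is
#' matched first, both are removed, and matching proceeds until spots or
#' modules are exhausted.
#'
#' @param spots A `spot_set` from [detect_spots()], or a named list of gene
#'   id vectors.
#' @param truth A cohort ground-truth list (element `truth` of
#'   [generate_cohort()] output).
#' @return Tibble with one row per planted module: `module`, `spot_id`
#'   (`NA` when unmatched), `jaccard`, `n_module_genes`, `n_spot_genes`.
#'   Attributes `n_unmatched_spots` and `n_unmatched_modules` count leftover
#'   items.
#' @export
match_modules <- function(spots, truth) {
  spot_genes <- if (inherits(spots, "spot_set")) {
    stats::setNames(spots$genes, spots$spot_id)
  } else {
    spots
  }
  gm <- truth$gene_module
  mods <- sort(unique(gm$module[!is.na(gm$module)]))
  mod_genes <- lapply(mods, function(m) gm$gene_id[!is.na(gm$module) & gm$module == m])
  names(mod_genes) <- as.character(mods)

  out <- tibble::tibble(module = mods, spot_id = NA_character_, jaccard = 0,
                        n_module_genes = lengths(mod_genes),
                        n_spot_genes = NA_integer_)
  if (length(spot_genes)) {
    J <- matrix(0, length(spot_genes), length(mods),
                dimnames = list(names(spot_genes), as.character(mods)))
    for (i in seq_along(spot_genes)) {
      for (j in seq_along(mods)) {
        a <- spot_genes[[i]]; b <- mod_genes[[j]]
        J[i, j] <- length(intersect(a, b)) / length(union(a, b))
      }
    }
    free_s <- rownames(J); free_m <- colnames(J)
    while (length(free_s) && length(free_m)) {
      sub <- J[free_s, free_m, drop = FALSE]
      best <- arrayInd(which.max(sub), dim(sub))
      s <- free_s[best[1]]; m <- free_m[best[2]]
      k <- match(as.integer(m), out$module)
      out$spot_id[k] <- s
      out$jaccard[k] <- sub[best]
      out$n_spot_genes[k] <- length(spot_genes[[s]])
      free_s <- setdiff(free_s, s); free_m <- setdiff(free_m, m)
    }
    attr(out, "n_unmatched_spots") <- length(free_s)
    attr(out, "n_unmatched_modules") <- length(free_m)
  } else {
    attr(out, "n_unmatched_spots") <- 0L
    attr(out, "n_unmatched_modules") <- length(mods)
  }
  out
}
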