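#' Assemble a mutational variance-covariance matrix (M-matrix)
#'
#' Builds the per-generation mutational (co)variance matrix from per-trait
#' mutational variances and pairwise mutational correlations:
#' `M_ii = V_m[i]`, `M_ij = r_g[i, j] sqrt(V_m[i] V_m[j])`. Missing
#' (inestimable) correlations propagate to flagged `NA` entries; any
#' submatrix used downstream must be complete (see [complete_submatrix()]).
#'
#' @param vm_by_trait named vector of per-generation mutational variances,
#'   all >= 0.
#' @param rg_matrix square matrix of mutational correlations in [-1, 1]
#'   (NA = inestimable); dimension/order must match `vm_by_trait`.
#' @param treatment optional label; `trait_means` optional named vector of
#'   trait means for [mean_standardize()].
#' @param trait_means optional named numeric vector of trait means.
#' @return object of class `m_matrix`: `M`, `traits`, `treatment`, `means`.
#' @export
assemble_m <- function(vm_by_trait, rg_matrix, treatment = NULL,
                       trait_means = NULL) {
  traits <- names(vm_by_trait)
  stopifnot(!is.null(traits), nrow(rg_matrix) == length(traits),
            ncol(rg_matrix) == length(traits))
  if (any(vm_by_trait < 0)) stop("negative V_m for an included trait")
  off <- rg_matrix[upper.tri(rg_matrix)]
  if (any(abs(off) > 1 + 1e-12, na.rm = TRUE)) {
    stop("correlations must lie in [-1, 1]")
  }
  sdv <- sqrt(vm_by_trait)
  M <- rg_matrix * outer(sdv, sdv)
  diag(M) <- vm_by_trait
  dimnames(M) <- list(traits, traits)
  out <- list(M = M, traits = traits, treatment = treatment,
              means = trait_means)
  class(out) <- "m_matrix"
  out
}

#' @export
print.m_matrix <- function(x, ...) {
  cat(sprintf("M-matrix (%s), %d traits; entries per generation\n",
              if (is.null(x$treatment)) "unlabeled" else x$treatment,
              length(x$traits)))
  print(signif(x$M, 4))
  invisible(x)
}

as_m_matrix <- function(m) {
  if (inherits(m, "m_matrix")) return(m)
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  traits <- rownames(m)
  if (is.null(traits)) traits <- paste0("trait", seq_len(nrow(m)))
  out <- list(M = m, traits = traits, treatment = NULL, means = NULL)
  class(out) <- "m_matrix"
  out
}

#' Largest complete principal submatrix
#'
#' Drops traits with flagged (NA) entries so downstream comparisons run on
#' a complete matrix, mirroring the study's restriction to the three traits
#' with estimable correlations.
#'
#' @param m an `m_matrix` (or plain matrix).
#' @param keep optional character vector of traits to keep instead.
#' @return an `m_matrix` on the retained traits.
#' @export
complete_submatrix <- function(m, keep = NULL) {
  m <- as_m_matrix(m)
  M <- m$M
  if (is.null(keep)) {
    keep <- m$traits
    while (any(is.na(M[keep, keep]))) {
      na_count <- rowSums(is.na(M[keep, keep, drop = FALSE]))
      keep <- keep[-which.max(na_count)]
    }
  }
  out <- list(M = M[keep, keep, drop = FALSE], traits = keep,
              treatment = m$treatment,
              means = if (!is.null(m$means)) m$means[keep] else NULL)
  class(out) <- "m_matrix"
  out
}

#' Random-skewers comparison of two M-matrices
#'
#' Draws random selection gradients (standard-normal vectors normalized to
#' unit length), pre-multiplies each by both matrices, and correlates the
#' two response vectors; the metric is the mean correlation over all draws.
#' The null distribution is the correlation between the responses to
#' independent random vectors (i.e. between pairs of random unit vectors),
#' and the p-value is the fraction of null correlations at or above the
#' metric — small p rejects the null of no structural similarity.
#'
#' The default correlation is the Pearson correlation of the response
#' vectors' components; `method = "cosine"` gives the uncentered vector
#' correlation instead.
#'
#' @param m1,m2 `m_matrix` objects (or plain matrices) of equal dimension,
#'   complete (no NA).
#' @param n_vectors number of random selection vectors (study value
#'   100,000; must be >= 1000 for the null calibration).
#' @param seed RNG seed.
#' @param method `"pearson"` (default) or `"cosine"`.
#' @return object of class `skewer_result`: `metric`, `p`, `null_quantiles`,
#'   `n_vectors`, `n_dropped` (degenerate zero-response draws), `seed`.
#' @export
random_skewers <- function(m1, m2, n_vectors = 100000, seed = 1L,
                           method = c("pearson", "cosine")) {
  method <- match.arg(method)
  m1 <- as_m_matrix(m1)$M
  m2 <- as_m_matrix(m2)$M
  if (!all(dim(m1) == dim(m2))) stop("dimension mismatch")
  if (any(is.na(m1)) || any(is.na(m2))) {
    stop("matrices must be complete; drop flagged traits first")
  }
  stopifnot(n_vectors >= 1000)
  k <- nrow(m1)
  set.seed(seed)
  B <- matrix(stats::rnorm(k * n_vectors), k, n_vectors)
  B <- sweep(B, 2, sqrt(colSums(B^2)), "/")
  R1 <- m1 %*% B
  R2 <- m2 %*% B
  corr_cols <- function(A, B2) {
    if (method == "pearson") {
      A <- sweep(A, 2, colMeans(A))
      B2 <- sweep(B2, 2, colMeans(B2))
    }
    num <- colSums(A * B2)
    den <- sqrt(colSums(A^2) * colSums(B2^2))
    num / den
  }
  rc <- corr_cols(R1, R2)
  dropped <- sum(!is.finite(rc))
  metric <- mean(rc[is.finite(rc)])
  # null: correlations between independent random unit vectors
  Bn1 <- matrix(stats::rnorm(k * n_vectors), k, n_vectors)
  Bn2 <- matrix(stats::rnorm(k * n_vectors), k, n_vectors)
  null <- corr_cols(Bn1, Bn2)
  null <- null[is.finite(null)]
  out <- list(metric = metric, p = mean(null >= metric),
              null_quantiles = stats::quantile(null, c(0.05, 0.5, 0.95)),
              n_vectors = n_vectors, n_dropped = dropped,
              seed = seed, method = method)
  class(out) <- "skewer_result"
  out
}

#' @export
print.skewer_result <- function(x, ...) {
  cat(sprintf(
    "Random skewers (%s, %d vectors): metric = %.3f, p(no similarity) = %.3f\n",
    x$method, x$n_vectors, x$metric, x$p))
  invisible(x)
}

#' Maximum evolvability
#'
#' The dominant eigenvalue of the M-matrix: the largest per-generation
#' mutational variance attainable in any direction of trait space.
#'
#' @param m complete symmetric `m_matrix` (or matrix); asymmetry beyond a
#'   1e-9 relative tolerance is an error.
#' @return e_max (same units as the matrix entries).
#' @export
evolvability_max <- function(m) {
  M <- as_m_matrix(m)$M
  if (any(is.na(M))) stop("matrix must be complete")
  asym <- max(abs(M - t(M)))
  if (asym > 1e-9 * max(abs(M))) stop("matrix asymmetric beyond tolerance")
  max(eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

#' Mean-standardize an M-matrix
#'
#' `M'_ij = M_ij / (mean_i mean_j)`, removing trait-scale differences so
#' matrix comparisons are not driven by measurement units.
#'
#' @param m `m_matrix` (or matrix).
#' @param trait_means named (or ordered) vector of trait means, all
#'   non-zero; defaults to the means stored on the object.
#' @return mean-standardized `m_matrix`.
#' @export
mean_standardize <- function(m, trait_means = NULL) {
  m <- as_m_matrix(m)
  mu <- if (is.null(trait_means)) m$means else trait_means
  if (is.null(mu)) stop("no trait means supplied or stored")
  if (!is.null(names(mu))) mu <- mu[m$traits]
  if (any(mu == 0)) stop("zero trait mean")
  out <- m
  out$M <- m$M / outer(mu, mu)
  out$means <- stats::setNames(rep(1, length(mu)), m$traits)
  out
}

#' Published per-generation mutational (co)variance matrices
#'
#' The study's reported M-matrices for the four fitness components under
#' the two MA environments (entries are per-generation changes in variance
#' and covariance due to mutation; the source table prints them multiplied
#' by 1e7, undone here). The haploid viability x haploid growth correlation
#' was inestimable under normal-MA and that entry is NA; comparisons
#' therefore use the complete 3-trait submatrix (diploid growth,
#' sporulation, haploid growth).
#'
#' @return list of two `m_matrix` objects, `normal` and `salt`.
#' @export
published_m_matrices <- function() {
  path <- system.file("extdata", "published_m_matrix.csv",
                      package = "mutarch", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  traits <- unique(df$trait_row)
  build <- function(trt) {
    d <- df[df$treatment == trt, ]
    M <- matrix(NA_real_, length(traits), length(traits),
                dimnames = list(traits, traits))
    for (i in seq_len(nrow(d))) {
      M[d$trait_row[i], d$trait_col[i]] <- d$value[i] * 1e-7
      M[d$trait_col[i], d$trait_row[i]] <- d$value[i] * 1e-7
    }
    out <- list(M = M, traits = traits, treatment = trt, means = NULL)
    class(out) <- "m_matrix"
    out
  }
  list(normal = build("normal"), salt = build("salt"))
}
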