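# Restricted-likelihood machinery shared by the variance-component and
# genetic-correlation fits. All models here are block-diagonal in some
# grouping unit (MA line, diploid parent), so the restricted log-likelihood
# is accumulated block by block:
#   -2 LL_R = sum log|V_i| + log|sum X_i' V_i^-1 X_i| + y'Py + (N-p) log 2pi
# with y'Py = sum y_i'V_i^-1 y_i - b' (X'V^-1X) b, b the GLS estimate.

# blocks: list of list(y, X, maker) where maker(par) returns the block V
reml_neg2ll_blocks <- function(V_list, y_list, X_list) {
  p <- ncol(X_list[[1]])
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  ytVy <- 0
  logdet <- 0
  n <- 0L
  for (i in seq_along(V_list)) {
    V <- V_list[[i]]
    n <- n + nrow(V)
    R <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(R)) return(Inf)
    logdet <- logdet + 2 * sum(log(diag(R)))
    yi <- y_list[[i]]
    Xi <- X_list[[i]]
    Vy <- backsolve(R, forwardsolve(t(R), yi))
    VX <- backsolve(R, forwardsolve(t(R), Xi))
    XtVX <- XtVX + crossprod(Xi, VX)
    XtVy <- XtVy + crossprod(Xi, Vy)[, 1]
    ytVy <- ytVy + sum(yi * Vy)
  }
  ld_xtvx <- determinant(XtVX, logarithm = TRUE)
  if (ld_xtvx$sign <= 0) return(Inf)
  b <- solve(XtVX, XtVy)
  val <- logdet + as.numeric(ld_xtvx$modulus) +
    (ytVy - sum(b * (XtVX %*% b))) + (n - p) * log(2 * pi)
  if (!is.finite(val)) Inf else val
}

# minimize fn over theta from several starts; returns best par and value
multi_start_optim <- function(fn, starts, lower = -Inf, upper = Inf,
                              polish = FALSE) {
  best <- NULL
  ctrl <- list(iter.max = 500, eval.max = 1000,
               rel.tol = 1e-12, x.tol = 1e-10)
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, fn, lower = lower, upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) stop("REML optimization failed at every start")
  if (polish) {
    # Nelder-Mead refinement squeezes out the last digits near the optimum
    po <- tryCatch(
      stats::optim(best$par, function(p) {
        if (any(p < lower) || any(p > upper)) return(1e12)
        fn(p)
      }, method = "Nelder-Mead",
      control = list(reltol = 1e-15, maxit = 5000)),
      error = function(e) NULL)
    if (!is.null(po) && is.finite(po$value) && po$value < best$objective) {
      best$par <- po$par
      best$objective <- po$value
    }
  }
  best
}

# ---- nested (parent / tetrad / spore strain / residual) model -------------

# build per-parent blocks from a haploid observation table; composite ids
# make the nesting explicit, and inconsistent keys (the same haploid strain
# under two tetrads, or a tetrad under two parents) are rejected
build_nested_blocks <- function(obs) {
  stopifnot(inherits(obs, "data.frame"))
  if (any(is.na(obs$parent)) || any(is.na(obs$tetrad))) {
    stop("nested model requires complete parent and tetrad keys")
  }
  strain <- obs$line
  chk <- unique(data.frame(strain = strain,
                           key = paste(obs$parent, obs$tetrad)))
  if (anyDuplicated(chk$strain)) {
    stop("non-nested keys: a haploid strain appears under two tetrads")
  }
  tet_id <- paste(obs$parent, obs$tetrad, sep = "\r")
  sp_id <- paste(tet_id, strain, sep = "\r")
  blocks <- lapply(split(seq_len(nrow(obs)), obs$parent), function(idx) {
    list(y = obs$value[idx],
         tet = as.integer(factor(tet_id[idx])),
         sp = as.integer(factor(sp_id[idx])),
         treatment = obs$treatment[idx][1],
         n = length(idx))
  })
  blocks
}

# V for one parent block given components c(parent, tetrad, spore, residual)
nested_block_V <- function(b, s2) {
  n <- b$n
  V <- matrix(s2[1], n, n)
  same_t <- outer(b$tet, b$tet, "==")
  same_s <- outer(b$sp, b$sp, "==")
  V <- V + s2[2] * same_t + s2[3] * same_s
  diag(V) <- diag(V) + s2[4]
  V
}

# -2 restricted LL for the nested model; s2_by_trt: named list of component
# vectors c(parent, tetrad, spore, residual) per treatment; X columns are
# treatment intercepts
nested_neg2ll <- function(blocks, s2_by_trt) {
  trts <- names(s2_by_trt)
  p <- length(trts)
  V_list <- vector("list", length(blocks))
  X_list <- vector("list", length(blocks))
  y_list <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    s2 <- s2_by_trt[[b$treatment]]
    V_list[[i]] <- nested_block_V(b, s2)
    X <- matrix(0, b$n, p)
    X[, match(b$treatment, trts)] <- 1
    X_list[[i]] <- X
    y_list[[i]] <- b$y
  }
  reml_neg2ll_blocks(V_list, y_list, X_list)
}

# method-of-moments-flavored starting component values
nested_mom_seed <- function(obs) {
  v <- stats::var(obs$value)
  if (!is.finite(v) || v <= 0) v <- 1
  rep(v / 4, 4)
}
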