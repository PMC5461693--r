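#' Lag-j structural correlation factor for PseKNC
#'
#' `theta_j = 1/(m (L-j-1)) * sum_s sum_t [P_t(r_s r_{s+1}) - P_t(r_{s+j} r_{s+j+1})]^2`
#' over the `m` local structural property scales, where `s` runs over the
#' `L-j-1` dinucleotide start positions that have a lag-`j` partner.
#'
#' @param spacer DNA string.
#' @param j lag (correlation order), `1 <= j <= L - 2`.
#' @param properties list of dinucleotide `property_table`s (the `m` scales).
#' @param standardized standardize each scale to mean 0 / sd 1 over the 16
#'   dinucleotides before use (the usual PseKNC convention).
#' @return nonnegative scalar.
#' @export
pseknc_theta <- function(spacer, j, properties = load_property_group("pseknc"),
                         standardized = TRUE) {
  L <- nchar(spacer)
  if (j < 1 || L - j - 1 < 1) stop("lag j = ", j, " too large for length ", L)
  P <- pseknc_property_matrix(properties, standardized)
  theta_all(spacer, j, P)[j]
}

# all theta_1..theta_lambda in one pass over the dinucleotide profile
theta_all <- function(spacer, lambda, P) {
  L <- nchar(spacer)
  ch <- strsplit(spacer, "")[[1]]
  din <- match(paste0(ch[-L], ch[-1]), DINUCS)   # L-1 dinucleotide indices
  vapply(seq_len(lambda), function(j) {
    s <- seq_len(L - j - 1)
    d <- P[din[s], , drop = FALSE] - P[din[s + j], , drop = FALSE]
    sum(d^2) / (ncol(P) * (L - j - 1))
  }, numeric(1))
}

pseknc_property_matrix <- function(properties, standardized) {
  P <- vapply(properties, function(tb) {
    stopifnot(tb$k == 2)
    tb$scores[DINUCS]
  }, numeric(16))
  if (standardized) P <- scale(P)[, , drop = FALSE]
  rownames(P) <- DINUCS
  P
}

#' Pseudo k-tuple nucleotide composition vector
#'
#' The normalized vector `[f_1/d, ..., f_{4^k}/d, w theta_1/d, ..., w theta_lambda/d]`
#' with `d = sum f + w sum theta`, where `f` are the overlapping k-tuple
#' frequencies of the spacer and `theta_j` the lag-`j` structural correlation
#' factors. With `k = 2`, `lambda = 1` the vector has 17 components and the
#' 16th is the TT term (alphabetical k-tuple order).
#'
#' @param spacer DNA string.
#' @param k k-tuple size.
#' @param lambda number of correlation lags (`lambda <= L - 2`).
#' @param w weight of the correlation terms (`w >= 0`).
#' @param properties list of dinucleotide `property_table`s.
#' @param standardized see [pseknc_theta()].
#' @return numeric vector of `4^k + lambda` components summing to 1, named
#'   `f_AA ... f_TT..., theta_1 ...`.
#' @export
pseknc_vector <- function(spacer, k = 2L, lambda = 1L, w = 0.5,
                          properties = load_property_group("pseknc"),
                          standardized = TRUE) {
  L <- nchar(spacer)
  stopifnot(k >= 1, lambda >= 0, w >= 0, L >= k)
  if (lambda > L - 2) stop("lambda = ", lambda, " exceeds L - 2 for length ", L)
  words <- kmer_words(k)
  obs <- substring(spacer, 1:(L - k + 1L), k:L)
  f <- tabulate(match(obs, words), 4^k) / (L - k + 1L)
  th <- if (lambda > 0) {
    theta_all(spacer, lambda, pseknc_property_matrix(properties, standardized))
  } else numeric(0)
  d <- sum(f) + w * sum(th)
  if (d <= 0) stop("degenerate normalization")
  setNames(c(f, w * th) / d,
           c(paste0("f_", words), if (lambda > 0) paste0("theta_", seq_len(lambda))))
}

#' PseKNC feature class
#'
#' One [pseknc_vector()] per record; default parameters `k = 2`,
#' `lambda = 1`, `w = 0.5` give 17 columns.
#'
#' @param dataset an `sgrna_dataset`.
#' @inheritParams pseknc_vector
#' @return a `feature_block`.
#' @export
pseknc_block <- function(dataset, k = 2L, lambda = 1L, w = 0.5,
                         properties = load_property_group("pseknc"),
                         standardized = TRUE) {
  sp <- spacers(dataset)
  v1 <- pseknc_vector(sp[1], k, lambda, w, properties, standardized)
  vals <- t(vapply(sp, pseknc_vector, v1, k = k, lambda = lambda, w = w,
                   properties = properties, standardized = standardized,
                   USE.NAMES = FALSE))
  feature_block("PseKNC", vals, paste0("pseknc_", names(v1)), dataset$id)
}

#' Select PseKNC parameters by cross-validated AUC
#'
#' Grid search over `(k, lambda, w)`: for each grid point and each labeled
#' dataset, an elastic-net model on the PseKNC block is scored by 3-fold
#' cross-validated AUC; the grid point with the largest mean AUC across
#' datasets wins. Ties break toward smaller `k`, then `lambda`, then `w`.
#'
#' @param datasets list of labeled `sgrna_dataset`s.
#' @param k_grid,lambda_grid,w_grid candidate values.
#' @param alpha elastic-net mixing parameter.
#' @param seed RNG seed for fold assignment.
#' @param properties,standardized see [pseknc_vector()].
#' @return list with `k`, `lambda`, `w` (the selected point) and `grid`
#'   (data.frame of mean AUC per point).
#' @export
select_pseknc_params <- function(datasets, k_grid = 2:6, lambda_grid = 1:15,
                                 w_grid = seq(0, 1, by = 0.1), alpha = 0.5,
                                 seed = 1L,
                                 properties = load_property_group("pseknc"),
                                 standardized = TRUE) {
  if (inherits(datasets, "sgrna_dataset")) datasets <- list(datasets)
  for (d in datasets) {
    if (length(unique(stats::na.omit(d$label))) < 2) {
      stop("parameter selection needs both efficiency classes in every dataset")
    }
  }
  grid <- expand.grid(k = k_grid, lambda = lambda_grid, w = w_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$k, grid$lambda, grid$w), , drop = FALSE]
  grid$mean_auc <- vapply(seq_len(nrow(grid)), function(i) {
    aucs <- vapply(datasets, function(d) {
      blk <- pseknc_block(d, grid$k[i], grid$lambda[i], grid$w[i],
                          properties, standardized)
      res <- eval_cv(bind_feature_blocks(blk), d$label, n_splits = 3,
                     iterations = 1, alpha = alpha, seed = seed)
      mean(res$auc)
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- which.max(grid$mean_auc)  # first max in (k, lambda, w) sort order
  list(k = grid$k[best], lambda = grid$lambda[best], w = grid$w[best],
       grid = grid)
}
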