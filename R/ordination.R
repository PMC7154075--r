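#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{D_{ij} = \sum_k |x_{ik} - x_{jk}| / \sum_k (x_{ik} + x_{jk})}
#' over samples (rows), computed with [vegan::vegdist()]. Values lie
#' in \[0, 1\]; the matrix is symmetric with a zero diagonal.
#'
#' @param x An [abundance_table()] or a non-negative samples x
#'   features matrix.
#' @return A symmetric dissimilarity matrix.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "abundance_table")) x$values else as.matrix(x)
  if (any(m < 0)) stop("negative abundances")
  zero <- rowSums(m) == 0
  if (any(zero)) {
    stop("undefined dissimilarity: all-zero sample(s) ",
         paste(rownames(m)[zero], collapse = ", "))
  }
  as.matrix(vegan::vegdist(m, method = "bray"))
}

# Gower-centred inner-product matrix of a dissimilarity matrix
.gower <- function(D) {
  A <- -0.5 * D^2
  rm <- rowMeans(A); gm <- mean(A)
  sweep(sweep(A, 1L, rm), 2L, rm) + gm
}

#' Cailliez additive constant
#'
#' Smallest constant c such that the off-diagonal dissimilarities
#' `D + c` admit an exact Euclidean embedding, obtained as the largest
#' real eigenvalue of the 2n x 2n companion matrix built from the
#' Gower-centred forms of `-D^2/2` and `-D/2`.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @return The constant c (0 when the matrix is already Euclidean).
#' @export
cailliez_constant <- function(D) {
  n <- nrow(D)
  delta1 <- .gower(D)
  A2 <- -0.5 * D
  rm <- rowMeans(A2); gm <- mean(A2)
  delta2 <- sweep(sweep(A2, 1L, rm), 2L, rm) + gm
  M <- rbind(cbind(matrix(0, n, n), 2 * delta1),
             cbind(-diag(n), -4 * delta2))
  ev <- eigen(M, only.values = TRUE)$values
  max(Re(ev[abs(Im(ev)) < 1e-8]))
}

#' Principal coordinate analysis with Cailliez correction
#'
#' Metric scaling of a dissimilarity matrix: Gower double-centring of
#' \eqn{-D^2/2} followed by eigendecomposition. When negative
#' eigenvalues beyond tolerance occur and `correction = "cailliez"`,
#' the Cailliez constant c is added to all off-diagonal
#' dissimilarities and the decomposition repeated, after which all
#' eigenvalues are non-negative up to tolerance and the inter-point
#' distances over all retained axes reproduce the corrected
#' dissimilarities.
#'
#' @param D Symmetric, non-negative dissimilarity matrix with zero
#'   diagonal (a `dist` is accepted).
#' @param correction `"cailliez"` (default) or `"none"`.
#' @param tol Relative tolerance on eigenvalues (default 1e-8 of the
#'   largest eigenvalue).
#' @return List of class `"ordination"`: `method` (`"PCoA"`),
#'   `coordinates` (samples x retained axes), `eigenvalues` (all, in
#'   decreasing order), `proportions` (share of positive-eigenvalue
#'   variance per retained axis), `correction_constant` (0 when no
#'   correction was needed).
#' @export
pcoa_ord <- function(D, correction = c("cailliez", "none"), tol = 1e-8) {
  correction <- match.arg(correction)
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-10))) {
    stop("D must be a symmetric matrix")
  }
  if (any(D < 0)) stop("D must be non-negative")
  if (any(abs(diag(D)) > 1e-12)) stop("D must have a zero diagonal")
  decomp <- function(Dm) eigen(.gower(Dm), symmetric = TRUE)
  e <- decomp(D)
  cc <- 0
  scale_tol <- tol * max(abs(e$values), 1e-300)
  if (correction == "cailliez" && min(e$values) < -scale_tol) {
    cc <- cailliez_constant(D)
    Dc <- D + cc
    diag(Dc) <- 0
    D <- Dc
    e <- decomp(D)
    scale_tol <- tol * max(abs(e$values))
  }
  keep <- e$values > scale_tol
  coords <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  pos <- sum(e$values[e$values > 0])
  structure(list(
    method = "PCoA",
    coordinates = coords,
    eigenvalues = e$values,
    proportions = e$values[keep] / pos,
    correction_constant = cc,
    corrected_D = D
  ), class = "ordination")
}

#' PCA of soil covariates
#'
#' Principal component analysis of the numeric soil covariates,
#' standardised to zero mean and unit variance (correlation
#' structure). Zero-variance columns are dropped with a warning.
#'
#' @param metadata data.frame of sample metadata; rownames or a
#'   `sample_id` column identify samples.
#' @param cols Optional character vector of columns to use; default:
#'   all numeric columns except `replicate`.
#' @return List of class `"ordination"`: `method` (`"PCA"`),
#'   `coordinates` (scores), `eigenvalues`, `proportions`,
#'   `loadings`.
#' @export
pca_soil <- function(metadata, cols = NULL) {
  if (is.null(cols)) {
    num <- vapply(metadata, is.numeric, logical(1))
    cols <- setdiff(names(metadata)[num], "replicate")
  }
  x <- as.matrix(metadata[cols])
  if (!is.null(metadata$sample_id)) rownames(x) <- metadata$sample_id
  if (nrow(x) < 2L || ncol(x) < 2L) stop("need >= 2 samples and >= 2 variables")
  if (anyNA(x)) stop("missing values in soil covariates")
  v <- apply(x, 2L, stats::var)
  if (any(v == 0)) {
    warning("dropping zero-variance column(s): ",
            paste(colnames(x)[v == 0], collapse = ", "))
    x <- x[, v > 0, drop = FALSE]
    if (ncol(x) < 2L) stop("fewer than 2 variable columns remain")
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  structure(list(
    method = "PCA",
    coordinates = pr$x,
    eigenvalues = ev,
    proportions = ev / sum(ev),
    loadings = pr$rotation,
    correction_constant = 0
  ), class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat(sprintf("%s ordination: %d samples, %d retained axes\n",
              x$method, nrow(x$coordinates), ncol(x$coordinates)))
  cat("variance explained:",
      paste0(sprintf("%.1f%%", 100 * utils::head(x$proportions, 4)),
             collapse = ", "), "\n")
  if (!is.null(x$correction_constant) && x$correction_constant > 0) {
    cat(sprintf("Cailliez constant: %.6g\n", x$correction_constant))
  }
  invisible(x)
}

#' Confidence ellipse of a 2D point group
#'
#' Ellipse around the group mean from the eigendecomposition of the
#' 2 x 2 covariance matrix, scaled by the chi-squared(2) quantile at
#' the confidence level (or an F-based small-sample quantile, material
#' with n = 3 points per group).
#'
#' @param points n x 2 matrix of coordinates, n >= 3.
#' @param level Confidence level (default 0.95).
#' @param quantile `"chisq"` (default) or `"f"` (Hotelling-type
#'   `2(n-1)/(n-2) F(level; 2, n-2)`).
#' @return List: `center`, `semi_axes` (major, minor), `angle`
#'   (radians of the major axis), `level`, `degenerate` (TRUE with
#'   < 3 points or a singular covariance, in which case the other
#'   fields may be NA).
#' @export
confidence_ellipse <- function(points, level = 0.95,
                               quantile = c("chisq", "f")) {
  quantile <- match.arg(quantile)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("points must be n x 2")
  n <- nrow(points)
  if (n < 3L) {
    return(list(center = colMeans(points), semi_axes = c(NA, NA),
                angle = NA, level = level, degenerate = TRUE))
  }
  S <- stats::cov(points)
  e <- eigen(S, symmetric = TRUE)
  if (e$values[2L] <= 1e-12 * max(e$values[1L], 1e-300)) {
    return(list(center = colMeans(points), semi_axes = c(NA, NA),
                angle = NA, level = level, degenerate = TRUE))
  }
  q <- if (quantile == "chisq") stats::qchisq(level, 2L) else
    2 * (n - 1) / (n - 2) * stats::qf(level, 2L, n - 2L)
  list(center = colMeans(points),
       semi_axes = sqrt(e$values * q),
       angle = atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]),
       level = level, degenerate = FALSE)
}
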