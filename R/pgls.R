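#' Brownian-motion covariance matrix of a tree
#'
#' Expected trait covariance between tips under Brownian motion:
#' `V[i, j]` is the shared branch length from the root to the most
#' recent common ancestor of tips i and j; the diagonal holds
#' root-to-tip depths.
#'
#' @param tree A rooted [ape::phylo] tree with branch lengths.
#' @return Symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
tree_vcv <- function(tree) {
  .rs_assert(inherits(tree, "phylo"), "tree must be a phylo object")
  .rs_assert(!is.null(tree$edge.length), "tree must have branch lengths")
  n <- length(tree$tip.label)
  depth <- ape::node.depth.edgelength(tree)  # distance from root per node
  mrca <- ape::mrca(tree)                    # n x n matrix of MRCA nodes
  V <- matrix(depth[mrca], n, n,
              dimnames = list(tree$tip.label, tree$tip.label))
  diag(V) <- depth[seq_len(n)]
  V
}

#' Phylogenetic generalized least squares regression
#'
#' Fits `y = a + b x` with error covariance proportional to the
#' Brownian-motion matrix of the tree: the GLS estimator
#' `(X' V^-1 X)^-1 X' V^-1 y`, solved through the Cholesky factor of V
#' (never an explicit inverse). The residual rate estimate is
#' `sigma2 = r' V^-1 r / (n - 2)`; the slope is tested with a Student t
#' on `n - 2` degrees of freedom. On a star phylogeny the fit reduces
#' exactly to ordinary least squares.
#'
#' @param traits A `data.frame` with columns `genome_id` (= tip labels),
#'   `x` and `y`; alternative column names can be given via `x`/`y`.
#' @param tree A rooted [ape::phylo] tree covering every `genome_id`.
#' @param x,y Names of the predictor and response columns.
#' @return A `pgls_fit` list: `intercept`, `slope`, `se` (length-2),
#'   `t`, `df`, `p`, `sigma2`, `residuals` (phylogenetically whitened),
#'   `n`.
#' @export
pgls_fit <- function(traits, tree, x = "x", y = "y") {
  .rs_assert(all(c("genome_id", x, y) %in% names(traits)),
             "traits must have columns genome_id, %s, %s", x, y)
  .rs_assert(!anyNA(traits[[x]]) && !anyNA(traits[[y]]),
             "traits must not contain missing values")
  .rs_assert(all(traits$genome_id %in% tree$tip.label),
             "every genome_id must be a tree tip")
  n <- nrow(traits)
  .rs_assert(n >= 3, "need at least 3 tips")
  V <- tree_vcv(tree)[traits$genome_id, traits$genome_id]
  U <- tryCatch(chol(V), error = function(e)
    stop("Brownian covariance is singular (zero-length root-to-tip path ",
         "or duplicated tip history); offending tips: ",
         paste(traits$genome_id[diag(V) <= 0], collapse = ", "),
         call. = FALSE))
  X <- cbind(1, traits[[x]])
  # whiten: V = U'U, so solving U' z = w gives z with identity covariance
  Xw <- forwardsolve(t(U), X)
  yw <- forwardsolve(t(U), traits[[y]])
  qrX <- qr(Xw)
  beta <- as.numeric(qr.coef(qrX, yw))
  rw <- yw - Xw %*% beta
  df <- n - 2
  sigma2 <- sum(rw^2) / df
  XtX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tstat <- beta[2] / se[2]
  p <- 2 * pt(-abs(tstat), df)
  p <- max(p, .Machine$double.xmin)  # perfect fits: overflow-safe floor
  structure(list(intercept = beta[1],
                 slope = beta[2],
                 se = setNames(se, c("intercept", "slope")),
                 t = tstat, df = df, p = p, sigma2 = sigma2,
                 residuals = setNames(as.numeric(rw), traits$genome_id),
                 n = n),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat(sprintf(
    "pgls_fit (n = %d): y = %.4g + %.4g x\n  t_%d = %.3f, p = %.3g, sigma2 = %.4g\n",
    x$n, x$intercept, x$slope, x$df, x$t, x$p, x$sigma2))
  invisible(x)
}
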