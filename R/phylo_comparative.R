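#' Phylogenetically independent contrasts (Felsenstein's algorithm)
#'
#' Prunes the tree to the trait's species, resolves polytomies
#' deterministically (zero-length branches, with optional jitter), and runs
#' the post-order contrast algorithm: at each internal node with child
#' values x1, x2 on adjusted branches b1, b2 the standardized contrast is
#' (x1 - x2) / sqrt(b1 + b2), the ancestral value is the branch-weighted
#' mean, and the node's parent branch is extended by b1 b2 / (b1 + b2).
#'
#' @param tree an \code{ape} phylo object, branch lengths required.
#' @param trait named numeric, names = tip labels. Tips without values are
#'   pruned; tips named in \code{trait} but absent from the tree are an
#'   error.
#' @param jitter added to zero-length branches after polytomy resolution
#'   (default 1e-8).
#' @return object of class \code{contrast_set}: list with
#'   \code{contrasts} (named by internal node number), \code{ancestral},
#'   \code{adjusted_bl}, \code{tree} (the pruned bifurcating tree),
#'   \code{trait_name}, \code{n_tips}.
#' @export
pic_contrasts <- function(tree, trait, jitter = 1e-8) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  missing_tips <- setdiff(names(trait), tree$tip.label)
  if (length(missing_tips) > 0)
    stop("trait species absent from tree: ",
         paste(missing_tips, collapse = ", "))
  if (anyNA(trait)) trait <- trait[!is.na(trait)]
  uncovered <- setdiff(tree$tip.label, names(trait))
  if (length(uncovered) > 0) tree <- ape::drop.tip(tree, uncovered)
  if (ape::Ntip(tree) < 2) stop("need at least 2 tips with trait values")
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  zero <- tree$edge.length <= 0
  if (any(zero)) tree$edge.length[zero] <- tree$edge.length[zero] + jitter
  if (any(tree$edge.length <= 0))
    stop("non-positive branch lengths remain after jitter")

  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  x <- numeric(ntip + nnode)
  x[seq_len(ntip)] <- trait[tree$tip.label]
  bl <- numeric(ntip + nnode)          # adjusted branch above each node
  edge <- tree$edge
  bl[edge[, 2]] <- tree$edge.length
  contrasts <- stats::setNames(numeric(nnode),
                               as.character(ntip + seq_len(nnode)))
  ord <- ape::reorder.phylo(tree, "postorder")
  po_edges <- ord$edge
  po_len <- nrow(po_edges)
  for (i in seq(1L, po_len, by = 2L)) {
    node <- po_edges[i, 1]
    c1 <- po_edges[i, 2]; c2 <- po_edges[i + 1, 2]
    stopifnot(po_edges[i + 1, 1] == node)
    b1 <- bl[c1]; b2 <- bl[c2]
    contrasts[as.character(node)] <- (x[c1] - x[c2]) / sqrt(b1 + b2)
    x[node] <- (x[c1] / b1 + x[c2] / b2) / (1 / b1 + 1 / b2)
    bl[node] <- bl[node] + b1 * b2 / (b1 + b2)
  }
  structure(
    list(contrasts = contrasts,
         ancestral = x[ntip + seq_len(nnode)],
         adjusted_bl = bl, tree = tree,
         trait_name = deparse(substitute(trait)), n_tips = ntip),
    class = "contrast_set"
  )
}

#' Through-origin regression of one contrast set on another
#'
#' Contrasts have arbitrary sign, so the regression is constrained through
#' the origin; the slope is tested two-sided against 0 with tips - 2
#' degrees of freedom.
#'
#' @param xc,yc \code{contrast_set} objects on the same (pruned) tree.
#' @return list: slope, se, r_squared, p_value, df, n_contrasts.
#' @export
pic_regression <- function(xc, yc) {
  cx <- xc$contrasts; cy <- yc$contrasts
  if (length(cx) != length(cy) || !all(names(cx) == names(cy)))
    stop("contrast sets are not on the same tree")
  if (length(cx) < 3) stop("need at least 3 contrasts")
  fit <- stats::lm(cy ~ cx + 0)
  # summary.lm warns on exact fits (e.g. a duplicated trait); the slope
  # and its zero p-value are still what we want to report
  sm <- suppressWarnings(summary(fit))
  list(slope = unname(stats::coef(fit)[1]),
       se = sm$coefficients[1, 2],
       r_squared = sm$r.squared,
       p_value = sm$coefficients[1, 4],
       df = fit$df.residual,
       n_contrasts = length(cx))
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits y = X beta + e with cov(e) = sigma^2 V where V_ij is the shared
#' root-to-MRCA path length of species i and j on the tree. Estimated by
#' explicit generalized least squares via the Cholesky factor of V.
#'
#' @param tree phylo object with branch lengths.
#' @param y named numeric response (names = tip labels).
#' @param X named numeric predictor, or a matrix/data frame with rownames =
#'   species (an intercept is always added).
#' @param jitter passed to zero-length branch handling as in
#'   \code{pic_contrasts}.
#' @return object of class \code{pgls_model}: coefficients, se, sigma2,
#'   residuals, standardized (whitened) residuals, fitted, vcov, df, n,
#'   species.
#' @export
pgls_fit <- function(tree, y, X, jitter = 1e-8) {
  y <- drop(y)
  if (is.null(dim(X)) || length(dim(X)) < 2)
    X <- matrix(drop(X), ncol = 1, dimnames = list(names(drop(X)), "x"))
  X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  sp <- intersect(tree$tip.label,
                  intersect(names(y)[!is.na(y)],
                            rownames(X)[stats::complete.cases(X)]))
  if (length(sp) < ncol(X) + 2) stop("too few complete cases for PGLS")
  tree <- ape::drop.tip(tree, setdiff(tree$tip.label, sp))
  if (!ape::is.binary(tree)) tree <- ape::multi2di(tree, random = FALSE)
  zero <- tree$edge.length <= 0
  if (any(zero)) tree$edge.length[zero] <- tree$edge.length[zero] + jitter
  sp <- tree$tip.label
  V <- ape::vcv(tree)
  yv <- y[sp]
  Xd <- cbind(`(Intercept)` = 1, X[sp, , drop = FALSE])
  L <- tryCatch(chol(V), error = function(e)
    stop("singular Brownian covariance; condition estimate: ",
         format(kappa(V))))
  wX <- backsolve(L, Xd, transpose = TRUE)
  wy <- backsolve(L, yv, transpose = TRUE)
  qrX <- qr(wX)
  if (qrX$rank < ncol(wX))
    stop("singular design matrix; condition estimate: ", format(kappa(wX)))
  beta <- qr.coef(qrX, wy)
  fitted <- drop(Xd %*% beta)
  resid <- yv - fitted
  n <- length(yv); p <- ncol(Xd)
  wres <- drop(backsolve(L, resid, transpose = TRUE))
  sigma2 <- sum(wres^2) / (n - p)
  XtViX_inv <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtViX_inv))
  names(se) <- names(beta) <- colnames(Xd)
  structure(
    list(coefficients = beta, se = se, sigma2 = sigma2,
         residuals = stats::setNames(resid, sp),
         std_residuals = stats::setNames(wres / sqrt(sigma2), sp),
         fitted = stats::setNames(fitted, sp),
         vcov = sigma2 * XtViX_inv, df = n - p, n = n, species = sp,
         predictors = colnames(X)),
    class = "pgls_model"
  )
}

#' @export
print.pgls_model <- function(x, ...) {
  cat("PGLS (Brownian covariance),", x$n, "species\n")
  tval <- x$coefficients / x$se
  print(data.frame(estimate = x$coefficients, se = x$se, t = tval,
                   p = 2 * stats::pt(-abs(tval), x$df)))
  invisible(x)
}

#' Predict from a PGLS model for species outside the tree
#'
#' Fixed-effects-only prediction: the new species has no phylogenetic
#' placement, so no covariance adjustment is applied.
#'
#' @param model a \code{pgls_model}.
#' @param newdata named numeric (one predictor) or matrix/data frame with
#'   the model's predictor columns.
#' @return numeric predictions.
#' @export
pgls_predict <- function(model, newdata) {
  if (is.null(dim(newdata)) || length(dim(newdata)) < 2) {
    stopifnot(length(model$predictors) == 1)
    newdata <- matrix(drop(newdata), ncol = 1,
                      dimnames = list(names(drop(newdata)),
                                      model$predictors))
  }
  newdata <- as.matrix(newdata)[, model$predictors, drop = FALSE]
  if (any(model$predictors %in% c("estai", "x")) &&
      any(newdata < 0 | newdata > 1))
    warning("predictor outside [0, 1]; estAI-scale predictors expected")
  drop(cbind(1, newdata) %*% model$coefficients)
}

#' Flag high-leverage contrast outliers
#'
#' Contrasts standardize trait differences by the square root of summed
#' branch lengths, so non-phylogenetic measurement noise between very
#' close relatives (e.g. two varieties of one species) explodes into a
#' single dominating contrast — the classic residual-plot outlier of
#' comparative growth analyses. This screen flags contrasts whose
#' magnitude exceeds k robust SDs (median absolute deviation scale) in
#' either trait and maps each back to a tip to drop: the descendant tip
#' with the shorter terminal branch (ties: the lexicographically larger
#' label). Removal is a user (or pipeline-configured) action.
#'
#' @param xc,yc \code{contrast_set} objects on the same tree.
#' @param k robust-SD threshold (default 4).
#' @return character vector of tip labels suggested for removal (empty
#'   when no contrast is flagged).
#' @export
contrast_outliers <- function(xc, yc, k = 4) {
  cx <- xc$contrasts; cy <- yc$contrasts
  flag <- function(v) {
    s <- stats::mad(v)
    if (s == 0) return(rep(FALSE, length(v)))
    abs(v - stats::median(v)) > k * s
  }
  nodes <- names(cx)[flag(cx) | flag(cy)]
  if (length(nodes) == 0) return(character(0))
  tree <- xc$tree
  ntip <- ape::Ntip(tree)
  term_bl <- stats::setNames(numeric(ntip), tree$tip.label)
  term_edge <- tree$edge[, 2] <= ntip
  term_bl[tree$tip.label[tree$edge[term_edge, 2]]] <-
    tree$edge.length[term_edge]
  drop <- vapply(nodes, function(nd) {
    tips_below <- ape::extract.clade(tree, as.integer(nd))$tip.label
    bl <- term_bl[tips_below]
    cand <- tips_below[bl == min(bl)]
    sort(cand, decreasing = TRUE)[1L]
  }, character(1))
  unique(unname(drop))
}

#' Flag residual outliers of a PGLS fit
#'
#' Species whose absolute standardized (whitened) residual exceeds k are
#' flagged for inspection; removal is a user decision, never automatic.
#'
#' @param model a \code{pgls_model}.
#' @param k threshold in residual standard deviations (default 3).
#' @return character vector of species ids.
#' @export
residual_outliers <- function(model, k = 3) {
  names(model$std_residuals)[abs(model$std_residuals) > k]
}
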