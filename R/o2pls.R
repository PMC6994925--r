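#' Log-transform, centre and scale an omics block for integration
#'
#' Applies \code{log2(x + pseudocount)}, then per-feature centring and
#' unit-variance scaling (n-1 convention), and returns the block in the
#' sample-by-feature orientation the O2PLS fit expects.
#'
#' @param x An \code{\link{omics_matrix}} or a feature-by-sample numeric
#'   matrix (non-negative when \code{log2 = TRUE}).
#' @param log2 Apply the log2 transform first (default TRUE).
#' @param pseudocount Offset added before the log (default 1).
#' @return Samples-by-features numeric matrix with column means 0 and
#'   column sds 1.
#' @export
scale_transform <- function(x, log2 = TRUE, pseudocount = 1) {
  v <- if (inherits(x, "omics_matrix")) x$values else x
  stopifnot(is.matrix(v), is.numeric(v))
  if (log2) {
    if (any(v + pseudocount <= 0, na.rm = TRUE)) {
      stop("non-positive values under the log transform", call. = FALSE)
    }
    v <- log2(v + pseudocount)
  }
  m <- t(v)
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature after transform: '",
         colnames(m)[sds == 0][1L], "'", call. = FALSE)
  }
  scale(m, center = TRUE, scale = sds)[, , drop = FALSE]
}

#' Pre-filter transcripts for integration
#'
#' Keeps genes showing potential differential signal — raw p below
#' \code{p_keep} in any of the supplied comparisons — union'd with the
#' top-variance genes (variance of log2 normalised counts + 1) up to a
#' configurable floor, and reports the retained count.
#'
#' @param om Count \code{\link{omics_matrix}}.
#' @param de_results List of \code{differential_result} objects.
#' @param p_keep Raw-p threshold (default 0.05); 1 keeps everything.
#' @param min_keep Floor: at least this many top-variance genes are
#'   retained (default 100).
#' @return The reduced count \code{omics_matrix}; attributes
#'   \code{n_p_hits} and \code{n_retained}.
#' @export
filter_transcripts <- function(om, de_results, p_keep = 0.05,
                               min_keep = 100) {
  stopifnot(inherits(om, "omics_matrix"))
  hits <- unique(unlist(lapply(de_results, function(r) {
    r$feature[r$p < p_keep]
  })))
  sf <- size_factors(om$values)
  lv <- log2(sweep(om$values, 2L, sf, `/`) + 1)
  vars <- apply(lv, 1L, stats::var)
  top <- rownames(om$values)[order(-vars)][seq_len(
    min(min_keep, nrow(om$values)))]
  keep <- union(hits, top)
  if (length(keep) == 0) stop("empty retention set", call. = FALSE)
  keep <- rownames(om$values)[rownames(om$values) %in% keep]
  out <- omics_matrix(om$values[keep, , drop = FALSE], om$samples,
                      features = if (is.null(om$features)) NULL else
                        om$features[match(keep, rownames(om$values)), ,
                                    drop = FALSE],
                      stage = om$stage)
  attr(out, "n_p_hits") <- length(hits)
  attr(out, "n_retained") <- length(keep)
  out
}

#' Fit a two-way orthogonal partial least squares (O2PLS) model
#'
#' Decomposes two column-centred (ideally unit-scaled) data blocks
#' sharing a sample axis into joint covariation, block-specific
#' (orthogonal) systematic variation and residual noise:
#' \deqn{X = T W' + T_{Yo} P_{Yo}' + E_X, \quad
#'       Y = U C' + U_{Xo} P_{Xo}' + E_Y.}
#' The K joint loadings W, C are the leading left/right singular vectors
#' of the cross-covariance \eqn{X'Y}; orthogonal components are
#' extracted as a single block from the SVD of \eqn{E'T} (respectively
#' \eqn{F'U}), which makes \eqn{W'W_{Yo} = 0} and \eqn{C'C_{Xo} = 0}
#' hold to machine precision; inner relations \eqn{T \approx U B_U},
#' \eqn{U \approx T B_T} link the blocks. Each joint component's sign is
#' fixed so the largest-magnitude entry of its W column is positive.
#'
#' @param X Samples-by-features matrix (e.g. lipids), centred.
#' @param Y Samples-by-features matrix (e.g. transcripts), centred, same
#'   rows as X.
#' @param K Number of joint components (>= 1).
#' @param nx,ny Numbers of X-side / Y-side orthogonal components
#'   (0 <= nx, ny <= K).
#' @return Object of class \code{o2pls} with elements \code{W}, \code{C}
#'   (joint loadings), \code{Tt}, \code{U} (joint scores), \code{W_yo},
#'   \code{P_yo}, \code{T_yo} and \code{C_xo}, \code{P_xo}, \code{U_xo}
#'   (orthogonal parts), \code{B_T}, \code{B_U} (inner regressions),
#'   \code{R2} (variance partition per block), residuals \code{E_x},
#'   \code{E_y}, dimensions and the call.
#' @examples
#' set.seed(1)
#' X <- scale(matrix(rnorm(200), 20, 10))
#' Y <- scale(X[, 1:5] %*% matrix(rnorm(40), 5, 8) + rnorm(160, sd = .1))
#' fit <- o2pls(X, Y, K = 2, nx = 0, ny = 0)
#' fit
#' @export
o2pls <- function(X, Y, K = 2, nx = 2, ny = 2) {
  stopifnot(is.matrix(X), is.matrix(Y))
  if (nrow(X) != nrow(Y)) {
    stop("X and Y must share the sample axis", call. = FALSE)
  }
  n <- nrow(X); p <- ncol(X); q <- ncol(Y)
  if (K < 1) stop("K must be >= 1", call. = FALSE)
  if (K + max(nx, ny) > min(n, p, q)) {
    stop("K + max(nx, ny) exceeds min(n, p, q); use fewer components",
         call. = FALSE)
  }
  if (nx > K || ny > K) {
    stop("block extraction limits orthogonal components to nx, ny <= K",
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(p))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(q))
  ssx <- sum(X^2); ssy <- sum(Y^2)

  sv <- svd(crossprod(X, Y), nu = K, nv = K)
  W <- sv$u; C <- sv$v
  for (k in seq_len(K)) {
    if (W[which.max(abs(W[, k])), k] < 0) {
      W[, k] <- -W[, k]; C[, k] <- -C[, k]
    }
  }
  Tt <- X %*% W; U <- Y %*% C

  Xd <- X
  W_yo <- P_yo <- T_yo <- NULL
  if (nx > 0) {
    E <- Xd - Tt %*% t(W)
    W_yo <- svd(crossprod(E, Tt), nu = nx)$u
    T_yo <- Xd %*% W_yo
    P_yo <- crossprod(Xd, T_yo) %*% .safe_solve(crossprod(T_yo))
    Xd <- Xd - T_yo %*% t(P_yo)
    Tt <- Xd %*% W
  }
  Yd <- Y
  C_xo <- P_xo <- U_xo <- NULL
  if (ny > 0) {
    F_ <- Yd - U %*% t(C)
    C_xo <- svd(crossprod(F_, U), nu = ny)$u
    U_xo <- Yd %*% C_xo
    P_xo <- crossprod(Yd, U_xo) %*% .safe_solve(crossprod(U_xo))
    Yd <- Yd - U_xo %*% t(P_xo)
    U <- Yd %*% C
  }

  B_U <- .safe_solve(crossprod(U)) %*% crossprod(U, Tt)
  B_T <- .safe_solve(crossprod(Tt)) %*% crossprod(Tt, U)

  E_x <- Xd - Tt %*% t(W)
  E_y <- Yd - U %*% t(C)
  joint_x <- sum((Tt %*% t(W))^2)
  joint_y <- sum((U %*% t(C))^2)
  orth_x <- if (nx > 0) sum((T_yo %*% t(P_yo))^2) else 0
  orth_y <- if (ny > 0) sum((U_xo %*% t(P_xo))^2) else 0
  R2 <- rbind(
    X = c(joint = joint_x / ssx, orthogonal = orth_x / ssx,
          noise = sum(E_x^2) / ssx),
    Y = c(joint = joint_y / ssy, orthogonal = orth_y / ssy,
          noise = sum(E_y^2) / ssy)
  )

  rownames(W) <- colnames(X); rownames(C) <- colnames(Y)
  dimnames(Tt) <- list(rownames(X), paste0("joint", seq_len(K)))
  dimnames(U) <- list(rownames(Y), paste0("joint", seq_len(K)))
  if (nx > 0) rownames(W_yo) <- rownames(P_yo) <- colnames(X)
  if (ny > 0) rownames(C_xo) <- rownames(P_xo) <- colnames(Y)

  structure(list(
    W = W, C = C, Tt = Tt, U = U,
    W_yo = W_yo, P_yo = P_yo, T_yo = T_yo,
    C_xo = C_xo, P_xo = P_xo, U_xo = U_xo,
    B_T = B_T, B_U = B_U,
    R2 = R2, E_x = E_x, E_y = E_y,
    K = K, nx = nx, ny = ny,
    dims = c(n = n, p = p, q = q),
    x_features = colnames(X), y_features = colnames(Y),
    call = match.call()
  ), class = "o2pls")
}

.safe_solve <- function(m) {
  tryCatch(solve(m), error = function(e) {
    stop("singular inner matrix (rank deficiency); ",
         "try fewer components", call. = FALSE)
  })
}

#' @export
print.o2pls <- function(x, digits = 3, ...) {
  cat(sprintf(
    "O2PLS model: %d samples, %d x %d y features; K=%d, nx=%d, ny=%d\n",
    x$dims["n"], x$dims["p"], x$dims["q"], x$K, x$nx, x$ny))
  cat("variance partition (fraction of total sum of squares):\n")
  print(round(x$R2, digits))
  invisible(x)
}

#' @export
summary.o2pls <- function(object, ...) {
  sing <- diag(crossprod(object$Tt, object$U))
  structure(list(
    model = object,
    score_correlations = vapply(seq_len(object$K), function(k) {
      stats::cor(object$Tt[, k], object$U[, k])
    }, 0),
    joint_covariance = sing,
    top_x = utils::head(top_loadings(object, "x", 5), 5),
    top_y = utils::head(top_loadings(object, "y", 5), 5)
  ), class = "summary.o2pls")
}

#' @export
print.summary.o2pls <- function(x, digits = 3, ...) {
  print(x$model, digits = digits)
  cat("\nper-component score correlations cor(T_k, U_k):\n")
  print(round(x$score_correlations, digits))
  cat("\ntop joint-loading features (x):\n")
  print(x$top_x, digits = digits)
  cat("top joint-loading features (y):\n")
  print(x$top_y, digits = digits)
  invisible(x)
}

#' Joint loadings of an O2PLS model
#'
#' @param object An \code{o2pls} fit.
#' @param side \code{"x"} (W) or \code{"y"} (C).
#' @param ... Unused.
#' @return Feature-by-component loading matrix.
#' @export
coef.o2pls <- function(object, side = c("x", "y"), ...) {
  side <- match.arg(side)
  if (side == "x") object$W else object$C
}

#' Predict one block from the other
#'
#' Removes the new block's orthogonal variation using the fitted
#' orthogonal filters, maps to joint scores, and reconstructs the other
#' block through the inner regression:
#' \eqn{\hat{Y} = (X - X W_{Yo} P_{Yo}') W B_T C'} and symmetrically for
#' \eqn{\hat{X}}.
#'
#' @param object An \code{o2pls} fit.
#' @param newdata Samples-by-features matrix of the block named by
#'   \code{from}.
#' @param from \code{"x"} to predict Y from X, \code{"y"} to predict X
#'   from Y.
#' @param ... Unused.
#' @return Predicted matrix for the opposite block.
#' @export
predict.o2pls <- function(object, newdata, from = c("x", "y"), ...) {
  from <- match.arg(from)
  stopifnot(is.matrix(newdata))
  if (from == "x") {
    if (ncol(newdata) != object$dims["p"]) {
      stop("newdata has ", ncol(newdata), " columns; expected ",
           object$dims["p"], call. = FALSE)
    }
    Xc <- newdata
    if (object$nx > 0) {
      Xc <- Xc - (Xc %*% object$W_yo) %*% t(object$P_yo)
    }
    (Xc %*% object$W) %*% object$B_T %*% t(object$C)
  } else {
    if (ncol(newdata) != object$dims["q"]) {
      stop("newdata has ", ncol(newdata), " columns; expected ",
           object$dims["q"], call. = FALSE)
    }
    Yc <- newdata
    if (object$ny > 0) {
      Yc <- Yc - (Yc %*% object$C_xo) %*% t(object$P_xo)
    }
    (Yc %*% object$C) %*% object$B_U %*% t(object$W)
  }
}

#' @export
fitted.o2pls <- function(object, ...) {
  list(
    X = object$Tt %*% t(object$W) +
      if (object$nx > 0) object$T_yo %*% t(object$P_yo) else 0,
    Y = object$U %*% t(object$C) +
      if (object$ny > 0) object$U_xo %*% t(object$P_xo) else 0
  )
}

#' @export
residuals.o2pls <- function(object, ...) {
  list(X = object$E_x, Y = object$E_y)
}

#' Score plot of an O2PLS model
#'
#' Scatter of the joint scores of both blocks for one component; points
#' on the diagonal indicate agreement of the two blocks' joint
#' structure.
#'
#' @param x An \code{o2pls} fit.
#' @param component Joint component to display (default 1).
#' @param col Point colours (e.g. group labels).
#' @param ... Passed to \code{plot}.
#' @export
plot.o2pls <- function(x, component = 1, col = 1, ...) {
  graphics::plot(x$Tt[, component], x$U[, component],
                 xlab = sprintf("T[, %d] (x joint score)", component),
                 ylab = sprintf("U[, %d] (y joint score)", component),
                 col = col, pch = 19, ...)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(x)
}

#' Variance partition of a fitted O2PLS model
#'
#' Fractions of each block's total sum of squares attributed to the
#' joint part, the block-specific orthogonal part and residual noise;
#' each row sums to 1.
#'
#' @param object An \code{o2pls} fit.
#' @return data.frame with columns \code{block}, \code{joint},
#'   \code{orthogonal}, \code{noise}.
#' @export
variance_decomposition <- function(object) {
  stopifnot(inherits(object, "o2pls"))
  data.frame(block = rownames(object$R2),
             joint = object$R2[, "joint"],
             orthogonal = object$R2[, "orthogonal"],
             noise = object$R2[, "noise"], row.names = NULL)
}

#' Top integration candidates by joint-loading magnitude
#'
#' Ranks features by the Euclidean norm of their row of the joint
#' loading matrix (W for the x block, C for the y block) and returns the
#' top k, mirroring candidate tables of integrative lipid-transcript
#' analyses (50 lipids / 100 genes by convention).
#'
#' @param object An \code{o2pls} fit.
#' @param side \code{"x"} or \code{"y"}.
#' @param k Number of candidates (default 50 for x, 100 for y).
#' @return data.frame \code{feature}, \code{loading_norm}, \code{rank},
#'   ordered by non-increasing magnitude (ties broken by feature id).
#' @export
top_loadings <- function(object, side = c("x", "y"), k = NULL) {
  stopifnot(inherits(object, "o2pls"))
  side <- match.arg(side)
  L <- if (side == "x") object$W else object$C
  if (is.null(k)) k <- if (side == "x") 50L else 100L
  if (k > nrow(L)) {
    warning("k = ", k, " exceeds feature count ", nrow(L),
            "; truncating")
    k <- nrow(L)
  }
  norms <- sqrt(rowSums(L^2))
  ord <- order(-norms, rownames(L))
  out <- data.frame(feature = rownames(L)[ord],
                    loading_norm = norms[ord],
                    rank = seq_along(ord), row.names = NULL,
                    stringsAsFactors = FALSE)
  utils::head(out, k)
}

#' Cross-validated selection of O2PLS component numbers
#'
#' Grid search over (K, nx, ny) triples minimising the summed held-out
#' reconstruction error \eqn{\|X - \hat{X}(Y)\|^2 + \|Y - \hat{Y}(X)\|^2}
#' over cross-validation folds. Fold assignment is deterministic given
#' the seed and stratified by \code{groups} when provided; ties are
#' broken towards fewer total components.
#'
#' @param X,Y Centred sample-by-feature matrices.
#' @param grid data.frame with columns \code{K}, \code{nx}, \code{ny}.
#' @param folds Number of folds (default 5).
#' @param groups Optional per-sample stratification labels.
#' @param seed Integer seed for the fold assignment (default 1).
#' @return List: selected \code{K}, \code{nx}, \code{ny} and the
#'   \code{cv} table of per-candidate errors.
#' @export
select_components <- function(X, Y, grid, folds = 5, groups = NULL,
                              seed = 1L) {
  if (is.null(grid) || nrow(as.data.frame(grid)) == 0) {
    stop("empty candidate grid", call. = FALSE)
  }
  grid <- as.data.frame(grid)
  stopifnot(all(c("K", "nx", "ny") %in% names(grid)))
  n <- nrow(X)
  set.seed(seed)
  fold <- integer(n)
  if (is.null(groups)) groups <- rep(1L, n)
  for (g in unique(groups)) {
    idx <- sample(which(groups == g))
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  err <- vapply(seq_len(nrow(grid)), function(i) {
    K <- grid$K[i]; nx <- grid$nx[i]; ny <- grid$ny[i]
    total <- 0
    for (f in seq_len(folds)) {
      tr <- fold != f
      if (sum(tr) < K + max(nx, ny) + 1) return(Inf)
      fit <- tryCatch(
        o2pls(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], K, nx, ny),
        error = function(e) NULL)
      if (is.null(fit)) return(Inf)
      te <- !tr
      xh <- predict(fit, Y[te, , drop = FALSE], from = "y")
      yh <- predict(fit, X[te, , drop = FALSE], from = "x")
      total <- total + sum((X[te, , drop = FALSE] - xh)^2) +
        sum((Y[te, , drop = FALSE] - yh)^2)
    }
    total
  }, 0)
  grid$cv_error <- err
  ord <- order(err, grid$K + grid$nx + grid$ny)
  best <- grid[ord[1L], ]
  list(K = best$K, nx = best$nx, ny = best$ny, cv = grid)
}
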