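#' Assemble standardized maps into a sample matrix
#'
#' Each map is flattened row-major (level-major: the 50 angular cells of
#' level 1, then level 2, ...) into one row of an `n x 4850` matrix.
#' Flag-masked cells are imputed by the per-column mean of unflagged
#' values within the specimen's group (falling back to the global column
#' mean for singleton groups or fully masked columns); the imputation
#' count is recorded.
#'
#' @param maps list of standardized `thickness_map`s on one grid.
#' @param labels group tags, one per map.
#' @param ids specimen ids, one per map (defaults to map metadata).
#' @return object of class `sample_matrix`: `X`, `labels`, `ids`,
#'   `n_imputed`, `grid`.
#' @export
assemble_matrix <- function(maps, labels, ids = NULL) {
  stopifnot(length(maps) == length(labels), length(maps) >= 1L)
  std <- .check_same_grid(maps)
  if (!std) stop("assemble_matrix requires standardized maps")
  if (is.null(ids))
    ids <- vapply(seq_along(maps), function(i) {
      id <- maps[[i]]$meta$id
      if (is.null(id) || is.na(id)) paste0("specimen-", i) else as.character(id)
    }, "")
  if (anyDuplicated(ids)) stop("contract error: duplicate specimen ids")
  n <- length(maps)
  X <- do.call(rbind, lapply(maps, function(m) as.numeric(t(m$values))))
  M <- do.call(rbind, lapply(maps, function(m) as.logical(t(m$mask))))
  n_imputed <- sum(M)
  if (n_imputed > 0L) {
    Xna <- X; Xna[M] <- NA_real_
    glob <- colMeans(Xna, na.rm = TRUE)
    glob[is.nan(glob)] <- colMeans(X)[is.nan(glob)]
    labels <- as.character(labels)
    for (g in unique(labels)) {
      rows <- which(labels == g)
      sub <- Xna[rows, , drop = FALSE]
      cm <- colMeans(sub, na.rm = TRUE)
      cm[is.nan(cm)] <- glob[is.nan(cm)]
      if (length(rows) == 1L) cm <- glob
      for (r in rows) {
        miss <- M[r, ]
        if (any(miss)) X[r, miss] <- cm[miss]
      }
    }
  }
  structure(list(X = X, labels = as.character(labels), ids = ids,
                 n_imputed = n_imputed, grid = dim(maps[[1L]]$values)),
            class = "sample_matrix")
}

# deterministic sign convention: the largest-|loading| entry positive
.sign_fix <- function(loadings, scores) {
  for (j in seq_len(ncol(loadings))) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(loadings = loadings, scores = scores)
}

#' Principal components analysis of map matrices
#'
#' Column-mean centered, unscaled PCA (cells share units) via singular
#' value decomposition, with a deterministic sign convention: the
#' largest-magnitude loading of every component is positive.
#'
#' @param x a `sample_matrix` or plain numeric matrix.
#' @param r number of components to keep (default all).
#' @param scale. unit-variance scaling; off by default and only offered
#'   as a labeled variant.
#' @return object of class `pca_model`: `mean`, `components` (columns),
#'   `eigenvalues`, `scores`, `scaled`.
#' @export
fit_pca <- function(x, r = NULL, scale. = FALSE) {
  X <- if (inherits(x, "sample_matrix")) x$X else as.matrix(x)
  n <- nrow(X)
  if (n < 3L) stop("need at least 3 specimens")
  pr <- stats::prcomp(X, center = TRUE, scale. = scale.)
  ev <- pr$sdev^2
  rank_ok <- sum(ev > ev[1L] * 1e-12)
  if (rank_ok == 0L || ev[1L] <= 0) stop("rank-0 data: all rows identical")
  if (is.null(r)) r <- length(ev)
  r <- min(r, ncol(pr$rotation))
  fixed <- .sign_fix(pr$rotation[, seq_len(r), drop = FALSE],
                     pr$x[, seq_len(r), drop = FALSE])
  structure(list(mean = pr$center, components = fixed$loadings,
                 eigenvalues = ev[seq_len(r)], scores = fixed$scores,
                 scaled = scale.,
                 scale = if (scale.) pr$scale else NULL,
                 ids = if (inherits(x, "sample_matrix")) x$ids else rownames(X),
                 labels = if (inherits(x, "sample_matrix")) x$labels else NULL),
            class = "pca_model")
}

#' Project new specimens into a fitted PCA space
#'
#' @param model a `pca_model`.
#' @param X matrix (rows = specimens) on the same cell grid.
#' @return score matrix.
#' @export
project_pca <- function(model, X) {
  X <- rbind(X)
  Xc <- sweep(X, 2L, model$mean)
  if (model$scaled) Xc <- sweep(Xc, 2L, model$scale, "/")
  Xc %*% model$components
}

#' One-sample Hotelling T-squared test
#'
#' Tests whether a group's multivariate mean equals a target vector:
#' `T2 = m (xbar - target)' S^-1 (xbar - target)` with S the sample
#' covariance; `F = T2 (m - p) / (p (m - 1))` on (p, m - p) degrees of
#' freedom.
#'
#' @param group_scores `m x p` matrix of scores.
#' @param target length-p vector.
#' @return object of class `hotelling_test`: `T2`, `F`, `df1`, `df2`,
#'   `p_value`.
#' @export
hotelling_one_sample <- function(group_scores, target) {
  X <- rbind(group_scores)
  m <- nrow(X); p <- ncol(X)
  if (m <= p) stop("need more specimens than dimensions (m > p)")
  if (length(target) != p) stop("target length must match score dimension")
  S <- stats::cov(X)
  Sinv <- tryCatch(solve(S), error = function(e)
    stop("singular covariance: use fewer PCs"))
  d <- colMeans(X) - as.numeric(target)
  T2 <- m * as.numeric(t(d) %*% Sinv %*% d)
  Fstat <- T2 * (m - p) / (p * (m - 1))
  pv <- stats::pf(Fstat, p, m - p, lower.tail = FALSE)
  structure(list(T2 = T2, F = Fstat, df1 = p, df2 = m - p, p_value = pv),
            class = "hotelling_test")
}

#' Canonical variates analysis
#'
#' Finds up to `min(g - 1, p)` axes maximizing between-group relative to
#' pooled within-group scatter, scaled so the pooled within-group
#' covariance is the identity in canonical space. Solved by whitening
#' the pooled within-group covariance (Cholesky) and an eigendecomposition
#' of the whitened between-group scatter; axis signs follow the PCA
#' convention.
#'
#' @param scores `n x p` score matrix (the default analysis protocol
#'   feeds the first 3 PC scores in).
#' @param labels group tags, one per row; every group needs >= 2 members.
#' @return object of class `cva_model`: `canonical_axes` (p x k),
#'   `eigenvalues`, `group_means` (canonical space), `grand_mean`,
#'   `pooled_within_covariance`, `scores` (canonical), `labels`.
#' @export
fit_cva <- function(scores, labels) {
  X <- rbind(scores)
  labels <- as.character(labels)
  stopifnot(nrow(X) == length(labels))
  groups <- unique(labels)
  g <- length(groups)
  p <- ncol(X)
  if (g < 2L) stop("need at least 2 groups")
  sizes <- table(labels)
  if (any(sizes < 2L)) stop("every group needs at least 2 members")
  n <- nrow(X)
  grand <- colMeans(X)
  W <- matrix(0, p, p)
  B <- matrix(0, p, p)
  gm <- matrix(0, g, p, dimnames = list(groups, NULL))
  for (i in seq_len(g)) {
    rows <- X[labels == groups[i], , drop = FALSE]
    mu <- colMeans(rows)
    gm[i, ] <- mu
    cr <- sweep(rows, 2L, mu)
    W <- W + crossprod(cr)
    B <- B + nrow(rows) * tcrossprod(mu - grand)
  }
  W <- W / (n - g)
  B <- B / (g - 1)
  Lc <- tryCatch(chol(W), error = function(e)
    stop("singular within-group scatter"))
  Linv <- backsolve(Lc, diag(p))      # W = Lc'Lc, Linv = Lc^-1
  Mw <- t(Linv) %*% B %*% Linv
  Mw <- (Mw + t(Mw)) / 2
  eg <- eigen(Mw, symmetric = TRUE)
  k <- min(g - 1L, p)
  axes <- Linv %*% eg$vectors[, seq_len(k), drop = FALSE]
  # canonical scores and sign fix
  Z <- sweep(X, 2L, grand) %*% axes
  fixed <- .sign_fix(axes, Z)
  axes <- fixed$loadings; Z <- fixed$scores
  gmz <- sweep(gm, 2L, grand) %*% axes
  structure(list(canonical_axes = axes, eigenvalues = eg$values[seq_len(k)],
                 group_means = gmz, grand_mean = grand,
                 pooled_within_covariance = W, scores = Z, labels = labels,
                 group_sizes = as.integer(sizes[groups])),
            class = "cva_model")
}

#' Project new specimens into a fitted CVA space
#'
#' @param model a `cva_model`.
#' @param scores matrix of PC scores (same columns the CVA was fit on).
#' @return canonical-space coordinates.
#' @export
project_cva <- function(model, scores) {
  sweep(rbind(scores), 2L, model$grand_mean) %*% model$canonical_axes
}

#' Typicality probability of a specimen for a group
#'
#' Squared distance to the group centroid in canonical space (where the
#' pooled within-group covariance is the identity, so Euclidean distance
#' is Mahalanobis distance) converted to an upper-tail probability.
#' `method = "chisq"` uses the chi-square distribution with as many
#' degrees of freedom as canonical axes; `method = "F"` applies the
#' small-sample correction for a new observation relative to a group of
#' size m.
#'
#' @param model a `cva_model`.
#' @param specimen canonical-space coordinate vector (see
#'   [project_cva()]).
#' @param group group label.
#' @param method `"chisq"` (default) or `"F"`.
#' @return object of class `typicality_result`: `D2`, `p`, `method`,
#'   `group`.
#' @export
typicality <- function(model, specimen, group, method = c("chisq", "F")) {
  method <- match.arg(method)
  if (!group %in% rownames(model$group_means))
    stop("unknown group: ", group)
  mu <- model$group_means[group, ]
  p <- length(mu)
  D2 <- sum((as.numeric(specimen) - mu)^2)
  if (method == "chisq") {
    prob <- stats::pchisq(D2, df = p, lower.tail = FALSE)
  } else {
    m <- model$group_sizes[match(group, rownames(model$group_means))]
    if (m <= p) stop("group too small for the F-based variant")
    Fstat <- (m * (m - p)) / (p * (m + 1) * (m - 1)) * D2
    prob <- stats::pf(Fstat, p, m - p, lower.tail = FALSE)
  }
  structure(list(D2 = D2, p = prob, method = method, group = group),
            class = "typicality_result")
}

#' Leave-one-out CVA classification
#'
#' Refits the CVA without each specimen in turn and assigns it to the
#' nearest group centroid in canonical space; reports the confusion
#' matrix and per-group accuracy.
#'
#' @param scores `n x p` score matrix.
#' @param labels group tags; every group needs >= 3 members.
#' @param ids optional specimen ids (duplicates are a contract error).
#' @return list with `confusion` (true x assigned), `accuracy`
#'   (per group) and `overall`.
#' @export
loo_classification <- function(scores, labels, ids = NULL) {
  X <- rbind(scores)
  labels <- as.character(labels)
  if (!is.null(ids) && anyDuplicated(ids))
    stop("contract error: duplicate specimen ids")
  sizes <- table(labels)
  if (any(sizes < 3L)) stop("every group needs at least 3 members for leave-one-out")
  groups <- sort(unique(labels))
  assigned <- character(nrow(X))
  for (i in seq_len(nrow(X))) {
    fit <- fit_cva(X[-i, , drop = FALSE], labels[-i])
    z <- project_cva(fit, X[i, , drop = FALSE])
    d2 <- rowSums(sweep(fit$group_means, 2L, as.numeric(z))^2)
    assigned[i] <- rownames(fit$group_means)[which.min(d2)]
  }
  confusion <- table(true = factor(labels, groups),
                     assigned = factor(assigned, groups))
  acc <- diag(as.matrix(confusion)) / as.integer(sizes[groups])
  list(confusion = confusion, accuracy = acc,
       overall = mean(assigned == labels))
}
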