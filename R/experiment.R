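#' Nearest-neighbour classification in an embedded space
#'
#' Assigns each test point the label of its nearest training point under the
#' Euclidean metric; exact ties go to the smallest training index.
#'
#' @param train_coords training coordinates, either `d x N` (columns =
#'   points, as returned by the embeddings' `Y`) or `N x d` with
#'   `points_in = "rows"`.
#' @param train_labels label per training point.
#' @param test_coords test coordinates, same orientation as `train_coords`.
#' @param points_in `"cols"` (default, matching embedding `Y` matrices) or
#'   `"rows"`.
#' @return Vector of predicted labels (same type as `train_labels`).
#' @export
nn_classify <- function(train_coords, train_labels, test_coords,
                        points_in = c("cols", "rows")) {
  points_in <- match.arg(points_in)
  tr <- as.matrix(train_coords); te <- as.matrix(test_coords)
  if (points_in == "cols") { tr <- t(tr); te <- t(te) }
  if (nrow(tr) == 0L) stop_invalid("empty training set")
  if (ncol(tr) != ncol(te)) stop_invalid("coordinate dimensions differ")
  d2 <- outer(rowSums(te^2), rowSums(tr^2), "+") - 2 * tcrossprod(te, tr)
  idx <- apply(d2, 1, which.min)    # which.min: first minimum = smallest index
  train_labels[idx]
}

#' Subject-grouped cross-validation folds
#'
#' Partitions subjects (not samples) into `n_folds` groups of near-equal
#' size, so that no subject appears in both a training and a test fold; all
#' images of a subject share its fold. Deterministic given `seed`.
#'
#' @param subjects subject identifier per sample.
#' @param n_folds number of folds (default 10); must not exceed the number
#'   of distinct subjects.
#' @param seed integer seed for the random subject shuffle (`NULL` uses the
#'   current RNG state).
#' @return An object of class `cv_plan`: list with `fold` (integer fold per
#'   sample), `subject_fold` (named fold per subject), `n_folds`, `seed`.
#' @export
subject_folds <- function(subjects, n_folds = 10L, seed = NULL) {
  us <- unique(subjects)
  if (length(us) < n_folds)
    stop_invalid("need at least ", n_folds, " distinct subjects for ",
                 n_folds, "-fold subject-grouped CV (got ", length(us), ")")
  perm <- with_seed(seed, sample(length(us)))
  sf <- rep(seq_len(n_folds), length.out = length(us))[order(perm)]
  names(sf) <- as.character(us)
  structure(list(fold = sf[as.character(subjects)],
                 subject_fold = sf, n_folds = as.integer(n_folds),
                 seed = seed),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("Subject-grouped CV plan: %d folds over %d subjects (%d samples)\n",
              x$n_folds, length(x$subject_fold), length(x$fold)))
  invisible(x)
}

#' Row-normalized confusion matrix
#'
#' Per-class recognition percentages: entry (i, j) is the percentage of
#' class-i samples predicted as class j; each non-empty row sums to 100.
#'
#' @param true true labels.
#' @param predicted predicted labels (same length).
#' @param classes class ordering for the rows/columns (default: levels of
#'   the true labels).
#' @return Square matrix of percentages; rows of classes absent from `true`
#'   are zero and flagged in attribute `empty_classes`.
#' @export
confusion_matrix <- function(true, predicted, classes = NULL) {
  if (length(true) != length(predicted))
    stop_invalid("label vectors must have equal length")
  if (is.null(classes)) classes <- levels(factor(true))
  true <- factor(true, levels = classes)
  predicted <- factor(predicted, levels = classes)
  if (any(is.na(true)) || any(is.na(predicted)))
    stop_invalid("labels outside the supplied class set")
  counts <- table(true, predicted)
  n <- rowSums(counts)
  pct <- 100 * counts / pmax(n, 1)
  pct <- matrix(as.numeric(pct), length(classes), length(classes),
                dimnames = list(true = classes, predicted = classes))
  attr(pct, "empty_classes") <- classes[n == 0]
  pct
}

# dimension grid used throughout the evaluation protocol: coarse sweep of
# [2, 100] in steps of 5, refined to steps of 1 over [2, 10]
#' Default embedded-dimension sweep grid
#'
#' Merges the coarse grid 2, 5, 10, ..., 100 (step 5 over [2, 100]) with the
#' fine grid 2..10 (step 1), deduplicated and sorted.
#' @return Integer vector of dimensions.
#' @export
default_dims <- function() {
  sort(unique(c(2L, seq(5L, 100L, 5L), 2:10)))
}

#' Cross-validated evaluation of embedding methods
#'
#' The full recognition protocol: subject-grouped k-fold cross-validation in
#' which, for every fold, each embedding is fitted on the training folds
#' only, the held-out fold is projected through the method's out-of-sample
#' extension, and a 1-NN classifier predicts its labels. Accuracy is
#' recorded for every (method, dimension, alpha) cell; spectral methods are
#' fitted once per fold at the largest requested dimension and sliced, since
#' their coordinates are nested.
#'
#' The discriminant constant alpha of KDIsomap is swept over `alphas`. With
#' `alpha_mode = "inner"` (default) alpha is chosen per dimension by an
#' inner subject-grouped cross-validation inside the training folds, so the
#' test fold never influences the choice; results are reported per
#' dimension with the selected alpha recorded per fold. With
#' `alpha_mode = "outer"` every (dimension, alpha) cell is reported and the
#' best cell is selected by test accuracy — an optimistic protocol, kept for
#' comparability with published sweeps.
#'
#' @param x feature matrix, rows = samples (e.g. from
#'   [lbp_feature_matrix()]).
#' @param labels class label per sample.
#' @param subjects subject identifier per sample.
#' @param methods subset of `c("pca", "lda", "kpca", "klda", "kisomap",
#'   "kdisomap")`.
#' @param dims dimensions to sweep (default [default_dims()]); LDA/KLDA are
#'   capped at c - 1, all methods at the training-set size.
#' @param alphas alpha grid for KDIsomap (default `seq(0, 1, 0.1)`).
#' @param k,sigma isomap neighbourhood size and Gaussian bandwidth.
#' @param n_folds outer folds (default 10).
#' @param seed integer seed controlling the fold assignment (the only source
#'   of randomness; results are bit-reproducible given the seed).
#' @param alpha_mode `"inner"` or `"outer"` (see above).
#' @param inner_folds folds of the inner alpha search (default 5).
#' @param auto_connect passed to the isomap fits.
#' @return An object of class `expression_experiment`: list with `cells` (a
#'   data frame of method, dim, alpha, mean accuracy, sd across folds, and
#'   per-fold accuracies), `predictions` (per-fold true/predicted labels for
#'   each method's best cell), `best` (best cell per method), `fold_details`
#'   (per-fold fitted-model scalars: beta, c*, chosen alpha), `plan`, and
#'   the call parameters.
#' @export
run_experiment <- function(x, labels, subjects,
                           methods = c("pca", "lda", "kpca", "klda",
                                       "kisomap", "kdisomap"),
                           dims = default_dims(), alphas = seq(0, 1, 0.1),
                           k = 10L, sigma = 1, n_folds = 10L, seed = 1L,
                           alpha_mode = c("inner", "outer"),
                           inner_folds = 5L, auto_connect = TRUE) {
  alpha_mode <- match.arg(alpha_mode)
  x <- as.matrix(x)
  labels <- factor(labels)
  methods <- match.arg(methods, several.ok = TRUE)
  plan <- subject_folds(subjects, n_folds = n_folds, seed = seed)
  nc <- nlevels(labels)
  cells <- list()
  fold_details <- list()
  predictions <- list()
  for (m in methods) {
    md <- method_dims(m, dims, nc)
    acc <- array(NA_real_, c(n_folds, length(md$dims),
                             if (m == "kdisomap" && alpha_mode == "outer")
                               length(alphas) else 1L))
    chosen_alpha <- matrix(NA_real_, n_folds, length(md$dims))
    fold_preds <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      tr <- which(plan$fold != f); te <- which(plan$fold == f)
      res <- tryCatch(
        eval_fold(m, x, labels, subjects, tr, te, md$dims, alphas,
                  k = k, sigma = sigma, alpha_mode = alpha_mode,
                  inner_folds = inner_folds, auto_connect = auto_connect),
        error = function(e) e)
      if (inherits(res, "error")) {
        fold_details[[length(fold_details) + 1L]] <-
          data.frame(method = m, fold = f, error = conditionMessage(res),
                     beta = NA, cstar = NA, alpha = NA)
        next
      }
      acc[f, , ] <- res$acc
      chosen_alpha[f, ] <- res$alpha
      fold_preds[[f]] <- res$preds
      fold_details[[length(fold_details) + 1L]] <-
        data.frame(method = m, fold = f, error = NA_character_,
                   beta = res$beta %||% NA, cstar = res$cstar %||% NA,
                   alpha = res$alpha[1] %||% NA)
    }
    # summarize cells
    if (m == "kdisomap" && alpha_mode == "outer") {
      for (di in seq_along(md$dims)) for (ai in seq_along(alphas)) {
        a <- acc[, di, ai]
        cells[[length(cells) + 1L]] <- data.frame(
          method = m, dim = md$dims[di], alpha = alphas[ai],
          mean = mean(a, na.rm = TRUE), sd = sd(a, na.rm = TRUE),
          n_folds_ok = sum(!is.na(a)))
      }
    } else {
      for (di in seq_along(md$dims)) {
        a <- acc[, di, 1]
        cells[[length(cells) + 1L]] <- data.frame(
          method = m, dim = md$dims[di],
          alpha = if (m == "kdisomap") mean(chosen_alpha[, di], na.rm = TRUE)
          else NA_real_,
          mean = mean(a, na.rm = TRUE), sd = sd(a, na.rm = TRUE),
          n_folds_ok = sum(!is.na(a)))
      }
    }
    predictions[[m]] <- fold_preds
  }
  cells <- do.call(rbind, cells)
  best <- do.call(rbind, lapply(split(cells, cells$method), function(g) {
    g[which.max(g$mean), , drop = FALSE]
  }))
  structure(list(cells = cells, best = best,
                 predictions = predictions,
                 fold_details = do.call(rbind, fold_details),
                 plan = plan, labels = labels,
                 params = list(methods = methods, dims = dims,
                               alphas = alphas, k = k, sigma = sigma,
                               n_folds = n_folds, seed = seed,
                               alpha_mode = alpha_mode)),
            class = "expression_experiment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

method_dims <- function(method, dims, n_classes) {
  dims <- sort(unique(as.integer(dims)))
  if (method %in% c("lda", "klda")) dims <- dims[dims <= n_classes - 1L]
  if (length(dims) == 0L) stop_invalid("no admissible dimensions for ", method)
  list(dims = dims)
}

# fit one method on the training fold, project the test fold, classify at
# every requested dimension (and alpha, for kdisomap); only rows indexed by
# `tr` ever reach a fit
eval_fold <- function(method, x, labels, subjects, tr, te, dims, alphas,
                      k, sigma, alpha_mode, inner_folds, auto_connect) {
  xtr <- x[tr, , drop = FALSE]; xte <- x[te, , drop = FALSE]
  ltr <- labels[tr]; lte <- labels[te]
  dims <- dims[dims <= length(tr)]
  dmax <- max(dims)
  slice_acc <- function(Ytr, Yte) {
    vapply(dims, function(d) {
      p <- nn_classify(Ytr[seq_len(d), , drop = FALSE], ltr,
                       Yte[seq_len(d), , drop = FALSE])
      100 * mean(p == lte)
    }, numeric(1))
  }
  slice_pred <- function(Ytr, Yte, d) {
    nn_classify(Ytr[seq_len(d), , drop = FALSE], ltr,
                Yte[seq_len(d), , drop = FALSE])
  }
  beta <- NULL; cstar <- NULL
  if (method == "kdisomap") {
    if (alpha_mode == "outer") {
      acc <- matrix(NA_real_, length(dims), length(alphas))
      preds <- NULL
      for (ai in seq_along(alphas)) {
        fit <- kdisomap(xtr, ltr, d = dmax, k = min(k, length(tr) - 1L),
                        sigma = sigma, alpha = alphas[ai],
                        auto_connect = auto_connect)
        Yte <- predict(fit, xte)
        acc[, ai] <- slice_acc(fit$Y, Yte)
        beta <- fit$beta; cstar <- fit$cstar
      }
      best <- which(acc == max(acc), arr.ind = TRUE)[1, ]
      fit <- kdisomap(xtr, ltr, d = dims[best[1]],
                      k = min(k, length(tr) - 1L), sigma = sigma,
                      alpha = alphas[best[2]], auto_connect = auto_connect)
      preds <- list(true = lte, pred = slice_pred(fit$Y, predict(fit, xte),
                                                  dims[best[1]]))
      return(list(acc = acc, alpha = rep(NA_real_, length(dims)),
                  preds = preds, beta = beta, cstar = cstar))
    }
    # inner alpha selection: subject-grouped CV inside the training folds
    a_sel <- select_alpha_inner(xtr, ltr, subjects[tr], dims, alphas,
                                k = k, sigma = sigma,
                                inner_folds = inner_folds,
                                auto_connect = auto_connect)
    acc <- matrix(NA_real_, length(dims), 1L)
    fits <- list()
    for (a in unique(a_sel)) {
      fit <- kdisomap(xtr, ltr, d = dmax, k = min(k, length(tr) - 1L),
                      sigma = sigma, alpha = a, auto_connect = auto_connect)
      Yte <- predict(fit, xte)
      sel <- which(a_sel == a)
      acc[sel, 1] <- slice_acc(fit$Y, Yte)[sel]
      fits[[as.character(a)]] <- fit
      beta <- fit$beta; cstar <- fit$cstar
    }
    di <- which.max(acc[, 1])
    fbest <- fits[[as.character(a_sel[di])]]
    preds <- list(true = lte,
                  pred = slice_pred(fbest$Y, predict(fbest, xte), dims[di]))
    return(list(acc = acc, alpha = a_sel, preds = preds,
                beta = beta, cstar = cstar))
  }
  fit <- switch(method,
                pca = pca_embed(xtr, min(dmax, ncol(xtr), length(tr) - 1L)),
                lda = lda_embed(xtr, ltr, dmax),
                kpca = kpca_embed(xtr, dmax, sigma = sigma),
                klda = klda_embed(xtr, ltr, dmax, sigma = sigma),
                kisomap = kisomap(xtr, d = dmax, k = min(k, length(tr) - 1L),
                                  auto_connect = auto_connect))
  if (method == "kisomap") cstar <- fit$cstar
  Yte <- predict(fit, xte)
  dims_fit <- dims[dims <= nrow(fit$Y)]
  acc <- matrix(NA_real_, length(dims), 1L)
  acc[seq_along(dims_fit), 1] <- vapply(dims_fit, function(d) {
    p <- nn_classify(fit$Y[seq_len(d), , drop = FALSE], ltr,
                     Yte[seq_len(d), , drop = FALSE])
    100 * mean(p == lte)
  }, numeric(1))
  di <- which.max(acc[, 1])
  preds <- list(true = lte,
                pred = slice_pred(fit$Y, Yte, dims_fit[min(di, length(dims_fit))]))
  list(acc = acc, alpha = rep(NA_real_, length(dims)), preds = preds,
       beta = beta, cstar = cstar)
}

select_alpha_inner <- function(xtr, ltr, str, dims, alphas, k, sigma,
                               inner_folds, auto_connect) {
  nf <- min(inner_folds, length(unique(str)))
  if (nf < 2L) return(rep(alphas[1], length(dims)))
  plan <- subject_folds(str, n_folds = nf, seed = 1L)
  dmax <- max(dims)
  acc <- array(NA_real_, c(nf, length(dims), length(alphas)))
  for (f in seq_len(nf)) {
    itr <- which(plan$fold != f); ite <- which(plan$fold == f)
    for (ai in seq_along(alphas)) {
      fit <- tryCatch(
        kdisomap(xtr[itr, , drop = FALSE], ltr[itr],
                 d = min(dmax, length(itr)), k = min(k, length(itr) - 1L),
                 sigma = sigma, alpha = alphas[ai],
                 auto_connect = auto_connect),
        error = function(e) NULL)
      if (is.null(fit)) next
      Yte <- predict(fit, xtr[ite, , drop = FALSE])
      for (di in seq_along(dims)) {
        d <- min(dims[di], nrow(fit$Y))
        p <- nn_classify(fit$Y[seq_len(d), , drop = FALSE], ltr[itr],
                         Yte[seq_len(d), , drop = FALSE])
        acc[f, di, ai] <- mean(p == ltr[ite])
      }
    }
  }
  vapply(seq_along(dims), function(di) {
    mu <- colMeans(acc[, di, , drop = FALSE][, 1, ], na.rm = TRUE)
    alphas[which.max(mu)]
  }, numeric(1))
}

#' @export
print.expression_experiment <- function(x, ...) {
  cat("Cross-validated embedding comparison\n")
  cat(sprintf("  %d folds, seed %s, alpha mode '%s'\n",
              x$params$n_folds, x$params$seed, x$params$alpha_mode))
  cat("  best cells:\n")
  b <- x$best
  for (i in seq_len(nrow(b)))
    cat(sprintf("    %-9s d = %-3d %s accuracy %.2f%% (sd %.2f)\n",
                b$method[i], b$dim[i],
                if (is.na(b$alpha[i])) "        "
                else sprintf("a = %.1f ", b$alpha[i]),
                b$mean[i], b$sd[i]))
  invisible(x)
}

#' @export
summary.expression_experiment <- function(object, ...) {
  print(object)
  invisible(object)
}

#' Accuracy-versus-dimension curves
#'
#' @param x an `expression_experiment`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.expression_experiment <- function(x, ...) {
  cl <- x$cells
  # one curve per method: best alpha per (method, dim)
  agg <- do.call(rbind, lapply(split(cl, list(cl$method, cl$dim), drop = TRUE),
                               function(g) g[which.max(g$mean), ]))
  methods <- unique(agg$method)
  dims <- sort(unique(agg$dim))
  M <- sapply(methods, function(m) {
    v <- rep(NA_real_, length(dims))
    g <- agg[agg$method == m, ]
    v[match(g$dim, dims)] <- g$mean
    v
  })
  matplot(dims, M, type = "b", pch = 19, lty = 1,
          col = hcl.colors(length(methods), "Dark 3"),
          xlab = "embedded dimension", ylab = "mean accuracy (%)", ...)
  legend("bottomright", legend = methods, pch = 19,
         col = hcl.colors(length(methods), "Dark 3"), cex = 0.8)
  invisible(x)
}

#' Best-cell confusion matrix of an experiment
#'
#' Pools the per-fold test predictions of a method's best cell and returns
#' the row-normalized confusion matrix.
#'
#' @param x an `expression_experiment`.
#' @param method method name (default: overall best).
#' @return Percentage matrix from [confusion_matrix()].
#' @export
experiment_confusion <- function(x, method = NULL) {
  if (is.null(method)) method <- x$best$method[which.max(x$best$mean)]
  preds <- x$predictions[[method]]
  preds <- preds[!vapply(preds, is.null, logical(1))]
  true <- unlist(lapply(preds, `[[`, "true"))
  pred <- unlist(lapply(preds, `[[`, "pred"))
  confusion_matrix(levels(x$labels)[true], levels(x$labels)[pred],
                   classes = levels(x$labels))
}

#' Write experiment outputs as CSV files
#'
#' Writes `accuracy_by_dimension.csv` (method, dim, alpha, mean, sd),
#' `best.csv`, and `confusion_<method>.csv` for every evaluated method, all
#' deterministic given the experiment seed.
#'
#' @param x an `expression_experiment`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(x$cells, file.path(dir, "accuracy_by_dimension.csv"),
            row.names = FALSE)
  write.csv(x$best, file.path(dir, "best.csv"), row.names = FALSE)
  for (m in names(x$predictions)) {
    cm <- tryCatch(experiment_confusion(x, m), error = function(e) NULL)
    if (!is.null(cm))
      write.csv(as.data.frame(cm), file.path(dir, paste0("confusion_", m, ".csv")))
  }
  invisible(dir)
}
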