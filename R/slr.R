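#' Periodic cross-validation fold assignment
#'
#' Assigns time-ordered samples to k groups cyclically: within each label,
#' the j-th sample (acquisition order, 0-based) goes to group `j mod k`.
#' Each fold then holds out one group. With 70 samples per label and k = 7,
#' every group holds 10 samples per label (60 train / 10 test per label per
#' fold; 300 training rows in five-choice, 120 in two-choice).
#'
#' @param labels Label per row, in acquisition order.
#' @param k Number of groups (default 7).
#' @return Integer fold id (1..k) per row.
#' @export
periodic_folds <- function(labels, k = 7) {
  if (k < 2) stop("`k` must be >= 2")
  if (min(table(labels)) < k) {
    stop("fewer than k = ", k, " samples for some label")
  }
  fold <- integer(length(labels))
  for (l in unique(labels)) {
    idx <- which(labels == l)
    fold[idx] <- ((seq_along(idx) - 1) %% k) + 1
  }
  fold
}

#' Rolling-window cross-validation splits
#'
#' Chronological splits for autocorrelated time series: every test block
#' strictly follows its training block in acquisition time. The expanding
#' variant is used: with block size `b = floor(n_per_label / (n_folds + 1))`,
#' split i trains on the first `i * b` samples per label and tests on the
#' next `b`.
#'
#' @param labels Label per row, in acquisition order.
#' @param n_folds Number of splits (default 3).
#' @return List of `n_folds` elements, each `list(train =, test =)` row
#'   indices.
#' @export
rolling_folds <- function(labels, n_folds = 3) {
  n_per <- min(table(labels))
  b <- n_per %/% (n_folds + 1)
  if (b < 1) {
    stop("insufficient rows: need at least ", n_folds + 1,
         " samples per label for ", n_folds, " rolling folds")
  }
  by_label <- lapply(unique(labels), function(l) which(labels == l))
  lapply(seq_len(n_folds), function(i) {
    train <- unlist(lapply(by_label, function(idx) idx[seq_len(i * b)]))
    test <- unlist(lapply(by_label, function(idx) idx[(i * b + 1):((i + 1) * b)]))
    list(train = sort(train), test = sort(test))
  })
}

#' Fit sparse multinomial logistic regression with automatic relevance determination
#'
#' Multinomial logistic regression sparsified by automatic relevance
#' determination (ARD): each feature f carries a precision hyperparameter
#' `alpha_f` acting as an adaptive ridge penalty shared across classes. The
#' fit alternates (i) a penalized-likelihood weight update over the active
#' features (L-BFGS), (ii) the MacKay evidence update of the penalty
#' precisions, `alpha_f <- gamma_f / sum_k w_fk^2` with well-determinedness
#' `gamma_fk = h_fk / (h_fk + alpha_f)` from the diagonal of the likelihood
#' Hessian (the naive `1/w^2` penalty update is degenerate: on separable data
#' it shrinks every weight geometrically to zero), and (iii) pruning of
#' features whose relevance precision `1 / (mean_k w_fk^2 + eps)` exceeds
#' `prune_alpha` -- their weights are exactly zero in the returned model. The
#' bias is never penalized or pruned. The procedure is deterministic given
#' the data.
#'
#' Features are standardized internally to training mean 0 / SD 1; the
#' transform is stored in the model and applied by [predict.slr_model()].
#'
#' @param x Numeric matrix, rows = samples, columns = features.
#' @param y Labels (numeric Hz or factor); at least two classes, at least two
#'   samples per class. Class order is fixed ascending.
#' @param max_outer Maximum ARD iterations (default 200).
#' @param tol Stop when the largest weight change falls below this (default
#'   1e-3 on standardized features, below which no test decision changes).
#' @param prune_alpha Precision cutoff for pruning (default 1e8).
#' @param inner_maxit L-BFGS iterations per weight update.
#' @return An `slr_model`: `weights` ((features+1) x classes, bias first row;
#'   pruned rows exactly zero), `active` (logical per feature), `classes`,
#'   `center`, `scale`, `converged`, `n_outer`, `alpha`.
#' @export
fit_slr <- function(x, y, max_outer = 200, tol = 1e-3, prune_alpha = 1e8,
                    inner_maxit = 100) {
  x <- as.matrix(x)
  classes <- sort(unique(y))
  K <- length(classes)
  if (K < 2) stop("need at least two classes")
  if (min(table(y)) < 2) stop("need at least two samples per class")
  yi <- match(y, classes)
  n <- nrow(x); p <- ncol(x)
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")

  eps <- 1e-12
  alpha_bias <- 1e-8
  active <- rep(TRUE, p)
  alpha <- rep(1, p)
  W <- matrix(0, p + 1, K)          # row 1 = bias
  converged <- FALSE
  n_outer <- 0

  neg_obj <- function(wvec, X1, al) slr_negobj(wvec, X1, yi, al, K)
  neg_grad <- function(wvec, X1, al) slr_neggrad(wvec, X1, yi, al, K)

  for (it in seq_len(max_outer)) {
    n_outer <- it
    act <- which(active)
    X1 <- cbind(1, xs[, act, drop = FALSE])
    al <- c(alpha_bias, alpha[act])
    w0 <- as.vector(W[c(1, act + 1), , drop = FALSE])
    fit <- stats::optim(w0, fn = neg_obj, gr = neg_grad, X1 = X1, al = al,
                        method = "L-BFGS-B",
                        control = list(maxit = inner_maxit))
    W_new <- matrix(0, p + 1, K)
    W_new[c(1, act + 1), ] <- matrix(fit$par, ncol = K)
    delta <- max(abs(W_new - W))
    W <- W_new
    # MacKay evidence update: alpha_f <- gamma_f / sum_k w_fk^2, where the
    # well-determinedness gamma_fk = h_fk / (h_fk + alpha_f) uses the diagonal
    # of the likelihood Hessian; this keeps data-supported features from the
    # degenerate all-pruned fixed point of the naive 1/w^2 update.
    Wa <- W[c(1, act + 1), , drop = FALSE]
    Z <- X1 %*% Wa
    Pm <- exp(Z - apply(Z, 1, max))
    Pm <- Pm / rowSums(Pm)
    h <- crossprod(X1^2, Pm * (1 - Pm))       # (|act|+1) x K
    gam <- h / (h + al)
    gamma_f <- rowSums(gam)[-1]
    ssw <- rowSums(Wa[-1, , drop = FALSE]^2)
    alpha[act] <- gamma_f / (ssw + eps)
    # relevance state: precision 1/(mean_k w_fk^2 + eps); prune above cutoff
    relevance <- rep(0, p)
    relevance[act] <- 1 / (ssw / K + eps)
    newly_pruned <- active & (relevance > prune_alpha)
    if (any(newly_pruned)) {
      active[newly_pruned] <- FALSE
      W[which(newly_pruned) + 1, ] <- 0
    }
    if (delta < tol && !any(newly_pruned)) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    message("fit_slr: ARD loop reached max_outer = ", max_outer,
            " without meeting tol; returning last iterate (flagged)")
  }
  structure(list(
    weights = W, active = active, classes = classes, center = center,
    scale = scale, converged = converged, n_outer = n_outer, alpha = alpha
  ), class = "slr_model")
}

#' @export
print.slr_model <- function(x, ...) {
  cat(sprintf("<slr_model> %d classes, %d/%d features active, %s after %d ARD iteration(s)\n",
              length(x$classes), sum(x$active), length(x$active),
              if (x$converged) "converged" else "NOT converged", x$n_outer))
  invisible(x)
}

#' Predict from a fitted sparse logistic regression model
#'
#' @param object An `slr_model`.
#' @param newx Matrix with the same feature count as the training data
#'   (unstandardized; the stored training transform is applied).
#' @param type `"class"` (default) or `"prob"` for softmax probabilities.
#' @param ... Unused.
#' @return Predicted labels, or an n x classes probability matrix. Argmax
#'   ties (probabilities within 1e-9) break toward the lowest class
#'   (ascending class order).
#' @export
predict.slr_model <- function(object, newx, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  if (ncol(newx) != length(object$center)) {
    stop("`newx` has ", ncol(newx), " features; model expects ",
         length(object$center))
  }
  xs <- sweep(sweep(newx, 2, object$center), 2, object$scale, "/")
  Z <- cbind(1, xs) %*% object$weights
  zmax <- apply(Z, 1, max)
  E <- exp(Z - zmax)
  P <- E / rowSums(E)
  colnames(P) <- as.character(object$classes)
  if (type == "prob") return(P)
  # argmax with ties (within numerical tolerance) resolved to the lowest class
  idx <- apply(P, 1, function(p) which(p >= max(p) - 1e-9)[1])
  object$classes[idx]
}

#' Define a decoding task
#'
#' @param labels Tone frequencies (Hz) to discriminate: 5 for five-choice,
#'   2 for two-choice.
#' @param ratio_class Optional difficulty class id (two-choice; see
#'   [two_choice_tasks()]).
#' @return A `decoding_task` with `kind` `"five_choice"` or `"two_choice"`.
#' @export
decoding_task <- function(labels, ratio_class = NA) {
  labels <- sort(labels)
  if (anyDuplicated(labels)) stop("task labels must be distinct")
  kind <- if (length(labels) == 2) "two_choice"
          else if (length(labels) == 5) "five_choice"
          else stop("a task has 2 (two-choice) or 5 (five-choice) labels")
  structure(list(kind = kind, labels = labels, ratio_class = ratio_class),
            class = "decoding_task")
}

#' Enumerate two-choice tasks stratified by frequency ratio
#'
#' All unordered pairs of the test frequencies, grouped into difficulty
#' classes by binning the octave distance `log2(f2/f1)` into quarter-octave
#' bins (floor). For the canonical five frequencies this yields 10 pairs in
#' exactly 6 ratio classes, from ~1/3 octave (hardest) to 2 octaves (easiest).
#'
#' @param freqs Tone frequencies in Hz (distinct).
#' @param bin_oct Bin width in octaves (default 0.25).
#' @return List of `decoding_task` objects; attribute `"pairs"` holds a data
#'   frame (`f1`, `f2`, `log2_ratio`, `ratio_class`).
#' @export
two_choice_tasks <- function(freqs = c(8000, 10000, 13000, 16000, 32000),
                             bin_oct = 0.25) {
  if (anyDuplicated(freqs)) stop("`freqs` must be distinct")
  freqs <- sort(freqs)
  pairs <- t(utils::combn(freqs, 2))
  lr <- log2(pairs[, 2] / pairs[, 1])
  bin <- floor(lr / bin_oct + 1e-9)
  df <- data.frame(f1 = pairs[, 1], f2 = pairs[, 2], log2_ratio = lr,
                   ratio_class = match(bin, sort(unique(bin))))
  tasks <- lapply(seq_len(nrow(df)), function(i) {
    decoding_task(c(df$f1[i], df$f2[i]), ratio_class = df$ratio_class[i])
  })
  attr(tasks, "pairs") <- df
  tasks
}

#' Run a decoding task on a feature table
#'
#' Cross-validated decoding of tone frequency: per fold, a sparse logistic
#' regression is fitted on the training rows (standardized per training fold)
#' and scored on the held-out rows. Accuracy is the percentage of correctly
#' discriminated test samples; the reported mean averages per-label accuracies
#' over all folds and test frequencies.
#'
#' @param table A `feature_table` containing every task label.
#' @param task A `decoding_task` (or label vector passed to
#'   [decoding_task()]).
#' @param scheme `"periodic"` (default) or `"rolling"` cross-validation.
#' @param k Groups for the periodic scheme (default 7).
#' @param n_folds Splits for the rolling scheme (default 3).
#' @param ... Passed to [fit_slr()].
#' @return A `decoding_result`: `mean_acc` (%), `fold_acc` (% per fold),
#'   `label_acc` (% per label, averaged over folds), `fold_label_acc`
#'   (folds x labels), plus task/band/kind/scheme/session metadata.
#' @export
run_task <- function(table, task, scheme = c("periodic", "rolling"),
                     k = 7, n_folds = 3, ...) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(table, "feature_table"))
  if (!inherits(task, "decoding_task")) task <- decoding_task(task)
  missing_lab <- setdiff(task$labels, unique(table$label))
  if (length(missing_lab)) {
    stop("feature table lacks label(s): ", paste(missing_lab, collapse = ", "))
  }
  tab <- subset_labels(table, task$labels)
  y <- tab$label
  splits <- if (scheme == "periodic") {
    fold <- periodic_folds(y, k)
    lapply(seq_len(k), function(f) list(train = which(fold != f),
                                        test = which(fold == f)))
  } else {
    rolling_folds(y, n_folds)
  }
  labs <- task$labels
  fold_label_acc <- matrix(NA_real_, length(splits), length(labs),
                           dimnames = list(NULL, as.character(labs)))
  for (f in seq_along(splits)) {
    sp <- splits[[f]]
    model <- fit_slr(tab$x[sp$train, , drop = FALSE], y[sp$train], ...)
    pred <- predict(model, tab$x[sp$test, , drop = FALSE])
    truth <- y[sp$test]
    for (li in seq_along(labs)) {
      m <- truth == labs[li]
      fold_label_acc[f, li] <- 100 * mean(pred[m] == truth[m])
    }
  }
  structure(list(
    mean_acc = mean(fold_label_acc),
    fold_acc = rowMeans(fold_label_acc),
    label_acc = colMeans(fold_label_acc),
    fold_label_acc = fold_label_acc,
    task = task, band = table$band, kind = table$kind, scheme = scheme,
    session_id = table$session_id
  ), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s on %s %s (%s CV): mean accuracy %.1f%%\n",
              x$task$kind, x$band, x$kind, x$scheme, x$mean_acc))
  invisible(x)
}
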