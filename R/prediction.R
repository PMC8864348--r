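#' Posterior maps of the latent processes
#'
#' Per-cell posterior mean (and 95% interval) of every latent process: each
#' ecological suitability `P_i`, the sampling effort `S`, and each mixture
#' `Q_i`. All quantities are computed draw by draw — in particular `Q_i` is
#' reconstructed from the joint draws of `alpha_i`, `P_i` and `S`, never by
#' combining averaged components (the mixture of means is not the mean of
#' mixtures).
#'
#' @param fit a [fit_pojsdm()] result.
#' @return data frame with columns `cell`, `cell_id`, `process`
#'   (`"P"`, `"S"` or `"Q"`), `taxon` (`NA` for `S`), `mean`, `lo95`,
#'   `hi95`.
#' @export
posterior_maps <- function(fit) {
  stopifnot(inherits(fit, "po_fit"))
  data <- fit$data
  pd <- .process_draws(fit)
  ids <- rownames(data$D_e[[1]])
  if (is.null(ids)) ids <- as.character(seq_len(data$n_cells))
  row <- function(mat, process, taxon) {
    q <- t(apply(mat, 1, quantile, probs = c(0.025, 0.975), names = FALSE))
    data.frame(cell = seq_len(data$n_cells), cell_id = ids,
               process = process, taxon = taxon,
               mean = rowMeans(mat), lo95 = q[, 1], hi95 = q[, 2],
               stringsAsFactors = FALSE)
  }
  out <- list(row(pd$S, "S", NA_character_))
  for (i in seq_len(data$n_taxa)) {
    out[[length(out) + 1L]] <- row(pd$P[[i]], "P", data$taxa[i])
    out[[length(out) + 1L]] <- row(pd$Q[[i]], "Q", data$taxa[i])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' AUC by the rank (Mann-Whitney) statistic
#'
#' Area under the ROC curve computed from average ranks of the scores
#' (ties receive their mid-rank). Equals trapezoidal integration of the ROC
#' curve.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 labels of the same length.
#' @return the AUC, or `NA` (with a warning) when only one class is
#'   present.
#' @export
auc_rank <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points and trapezoidal AUC
#'
#' @inheritParams auc_rank
#' @return data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1); the trapezoidal AUC is attached as attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.integer(labels[keep])
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  # collapse tied thresholds
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(l); fp <- cumsum(1L - l)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / max(n1, 1L))
  fpr <- c(0, fp[last] / max(n0, 1L))
  thr <- c(Inf, s[last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(data.frame(threshold = thr, fpr = fpr, tpr = tpr),
            auc = if (n1 == 0L || n0 == 0L) NA_real_ else auc)
}

# seeded stratified partition of cell indices into k folds
.make_folds <- function(strata, k, seed) {
  set.seed(seed)
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- which(strata == s)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' k-fold cross-validated ROC/AUC
#'
#' Cells with observed responses are partitioned into `k` stratified,
#' seed-reproducible folds (stratification preserves the joint
#' presence/absence pattern across responses, so each fold sees a similar
#' class balance). For each fold the model is refit with the fold's
#' responses masked as missing; the held-out cells are then scored by their
#' imputed posterior probabilities — the mixture `Q_i` for taxon responses
#' and `S` for the complementary response — and ROC/AUC computed against
#' the held-out 0/1 labels.
#'
#' @param data a [model_data()] object.
#' @param priors a [po_priors()] object.
#' @param config a [fit_config()] used for each refit.
#' @param k number of folds (>= 2).
#' @param seed seed for the fold partition.
#' @param responses which responses to validate: `"taxa"`, `"y_c"` or
#'   `"both"` (default `"taxa"`).
#' @return an object of class `po_cv`: `per_fold` (fold x response AUC
#'   table; `NA` with a reason when a fold holds a single class),
#'   `per_response` pooled AUC by response, `pooled_auc` over all held-out
#'   scores, `auc_range` across folds, `folds` assignment, and pooled `roc`
#'   points.
#' @export
kfold_auc <- function(data, priors = po_priors(), config = fit_config(),
                      k = 5, seed = 1,
                      responses = c("taxa", "y_c", "both")) {
  responses <- match.arg(responses)
  stopifnot(inherits(data, "po_model_data"), k >= 2)
  use_taxa <- responses %in% c("taxa", "both")
  use_yc <- responses %in% c("y_c", "both")
  obs_mat <- cbind(if (use_taxa) !is.na(data$y) else NULL,
                   if (use_yc) !is.na(data$y_c) else NULL)
  eligible <- which(rowSums(obs_mat) > 0L)
  if (length(eligible) < k) stop("not enough observed cells for k folds")
  strata <- apply(cbind(if (use_taxa) data$y[eligible, , drop = FALSE] else NULL,
                        if (use_yc) data$y_c[eligible] else NULL),
                  1, paste, collapse = "/")
  fold_of <- .make_folds(strata, k, seed)
  folds <- integer(data$n_cells)
  folds[eligible] <- fold_of

  resp_names <- c(if (use_taxa) data$taxa else character(0),
                  if (use_yc) "y_c" else character(0))
  scores <- labels <- resp <- fold_id <- list()
  for (f in seq_len(k)) {
    held <- eligible[fold_of == f]
    y_tr <- data$y
    y_c_tr <- data$y_c
    if (use_taxa) y_tr[held, ] <- NA_integer_
    if (use_yc) y_c_tr[held] <- NA_integer_
    dat_f <- data
    dat_f$y <- y_tr
    dat_f$y_c <- y_c_tr
    fit <- suppressWarnings(fit_pojsdm(dat_f, priors, config))
    pd <- .process_draws(fit, held)
    if (use_taxa) {
      for (i in seq_len(data$n_taxa)) {
        ok <- !is.na(data$y[held, i])
        scores[[length(scores) + 1L]] <- rowMeans(pd$Q[[i]])[ok]
        labels[[length(labels) + 1L]] <- data$y[held, i][ok]
        resp[[length(resp) + 1L]] <- rep(data$taxa[i], sum(ok))
        fold_id[[length(fold_id) + 1L]] <- rep(f, sum(ok))
      }
    }
    if (use_yc) {
      ok <- !is.na(data$y_c[held])
      scores[[length(scores) + 1L]] <- rowMeans(pd$S)[ok]
      labels[[length(labels) + 1L]] <- data$y_c[held][ok]
      resp[[length(resp) + 1L]] <- rep("y_c", sum(ok))
      fold_id[[length(fold_id) + 1L]] <- rep(f, sum(ok))
    }
  }
  sc <- unlist(scores); lb <- unlist(labels)
  rp <- unlist(resp); fd <- unlist(fold_id)
  per_fold <- do.call(rbind, lapply(seq_len(k), function(f)
    do.call(rbind, lapply(resp_names, function(r) {
      m <- fd == f & rp == r
      a <- if (length(unique(lb[m])) < 2L) NA_real_
           else auc_rank(sc[m], lb[m])
      data.frame(fold = f, response = r, n = sum(m), auc = a,
                 stringsAsFactors = FALSE)
    }))))
  fold_aucs <- vapply(seq_len(k), function(f) {
    m <- fd == f
    if (length(unique(lb[m])) < 2L) NA_real_ else auc_rank(sc[m], lb[m])
  }, numeric(1))
  per_response <- vapply(resp_names, function(r)
    auc_rank(sc[rp == r], lb[rp == r]), numeric(1))
  structure(
    list(k = k, per_fold = per_fold,
         per_response = per_response,
         pooled_auc = auc_rank(sc, lb),
         auc_range = range(fold_aucs, na.rm = TRUE),
         folds = folds, roc = roc_curve(sc, lb),
         scores = sc, labels = lb, response = rp, fold = fd),
    class = "po_cv"
  )
}

#' @export
print.po_cv <- function(x, ...) {
  cat(sprintf("po_cv: %d folds, pooled AUC %.3f (fold range %.3f-%.3f)\n",
              x$k, x$pooled_auc, x$auc_range[1], x$auc_range[2]))
  invisible(x)
}
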