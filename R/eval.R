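# Per-case success judgement, the error taxonomy (overlapped pair,
# missed rib, non-rib labeled), and cohort success rates.

#' Judge sequence-labeling success for one case
#'
#' Matches each predicted rib cluster to ground truth by voxel overlap.
#' A truth rib is *covered* by the predicted cluster containing at least
#' half of its voxels.  The case succeeds iff every truth rib is covered
#' by a cluster carrying its correct ordinal and side, clusters and truth
#' ribs correspond one-to-one, and no cluster lies mostly on non-rib
#' structures or background.  Failures are classified exhaustively:
#' * `overlapped_pair` - one cluster covers two or more truth ribs;
#' * `missed_rib` - a truth rib covered by no cluster, or covered by a
#'   cluster carrying the wrong ordinal or side;
#' * `nonrib_labeled` - a cluster whose voxels lie mostly outside the
#'   truth ribs.
#'
#' @param labels predicted [label_volume()] from [label_sequence()].
#' @param report the matching `rib_label_report`.
#' @param truth a `rib_phantom`, its `truth` list, or a [label_volume()]
#'   of ground-truth rib labels coded like the phantom's
#'   (left i -> i, right i -> n_pairs + i).
#' @param n_pairs number of rib pairs in the truth coding (default 12);
#'   ignored when `truth` carries its own table.
#' @return An object of class `case_result`: `case_id`, `success`,
#'   `errors` (subset of the three classes), `pairs` (per-pair
#'   correctness).
#' @export
case_success <- function(labels, report, truth, n_pairs = 12L) {
  stopifnot(inherits(labels, "label_volume"))
  tr <- normalize_truth(truth, n_pairs)
  if (!identical(dim(labels$voxels), dim(tr$rib_labels)))
    stop("parameter error: prediction and truth geometries differ", call. = FALSE)

  pred <- labels$voxels
  p <- report$n_pairs
  pred_table <- if (p > 0L)
    data.frame(label = c(seq_len(p), p + seq_len(p)),
               ordinal = c(seq_len(p), seq_len(p)),
               side = rep(c("left", "right"), each = p))
  else data.frame(label = integer(0), ordinal = integer(0), side = character(0))

  errors <- character(0)
  # overlap tally between predicted labels and truth ribs
  sel <- pred > 0L
  ov <- if (any(sel)) table(pred = pred[sel], truth = tr$rib_labels[sel]) else NULL
  truth_sizes <- table(tr$rib_labels[tr$rib_labels > 0L])

  # coverage: which cluster holds >= 50% of each truth rib
  cover <- setNames(rep(NA_integer_, nrow(tr$rib_table)), tr$rib_table$label)
  for (tl in tr$rib_table$label) {
    tls <- as.character(tl)
    if (!is.null(ov) && tls %in% colnames(ov)) {
      hits <- ov[, tls]
      best <- which.max(hits)
      if (hits[best] >= 0.5 * truth_sizes[[tls]])
        cover[tls] <- as.integer(rownames(ov)[best])
    }
  }
  # overlapped_pair: a cluster covering two or more truth ribs
  covered_by <- table(cover[!is.na(cover)])
  if (any(covered_by >= 2L)) errors <- c(errors, "overlapped_pair")

  # nonrib_labeled: cluster mostly outside truth ribs
  for (pl in pred_table$label) {
    pls <- as.character(pl)
    csize <- sum(pred == pl)
    onrib <- if (!is.null(ov) && pls %in% rownames(ov))
      sum(ov[pls, colnames(ov) != "0"]) else 0
    if (csize > 0L && onrib < 0.5 * csize) {
      errors <- c(errors, "nonrib_labeled")
      break
    }
  }

  # per-truth-rib correctness; wrong ordinal/side or no coverage -> missed
  pair_rows <- list()
  missed <- FALSE
  for (r in seq_len(nrow(tr$rib_table))) {
    tl <- tr$rib_table$label[r]
    cl <- cover[as.character(tl)]
    ok <- FALSE
    if (!is.na(cl)) {
      hit <- pred_table[pred_table$label == cl, , drop = FALSE]
      ok <- nrow(hit) == 1L && hit$ordinal == tr$rib_table$ordinal[r] &&
        hit$side == tr$rib_table$side[r]
    }
    if (!ok) missed <- TRUE
    pair_rows[[r]] <- data.frame(ordinal = tr$rib_table$ordinal[r],
                                 side = tr$rib_table$side[r], correct = ok)
  }
  if (missed) errors <- c(errors, "missed_rib")
  errors <- unique(errors)
  pairs <- do.call(rbind, pair_rows)
  structure(list(case_id = report$case_id, success = length(errors) == 0L,
                 errors = errors, pairs = pairs),
            class = "case_result")
}

normalize_truth <- function(truth, n_pairs) {
  if (inherits(truth, "rib_phantom")) truth <- truth$truth
  if (is.list(truth) && !inherits(truth, "label_volume") &&
      all(c("rib_labels", "rib_table") %in% names(truth)))
    return(truth)
  if (inherits(truth, "label_volume")) {
    labs <- sort(unique(truth$voxels[truth$voxels > 0L]))
    tab <- data.frame(label = labs,
                      ordinal = ifelse(labs > n_pairs, labs - n_pairs, labs),
                      side = ifelse(labs > n_pairs, "right", "left"))
    return(list(rib_labels = truth$voxels, rib_table = tab))
  }
  stop("parameter error: unsupported truth object", call. = FALSE)
}

#' @export
print.case_result <- function(x, ...) {
  cat(sprintf("<case_result>%s %s%s\n",
              if (!is.na(x$case_id)) paste0(" case ", x$case_id, ":") else "",
              if (x$success) "SUCCESS" else "FAILURE",
              if (length(x$errors)) paste0(" [", paste(x$errors, collapse = ", "), "]") else ""))
  invisible(x)
}

#' Cohort success rate with 95% confidence interval
#'
#' The success rate is the percentage of cases in which all rib pairs are
#' labeled in a complete, correct sequence.  The 95% CI uses the normal
#' approximation, clipped to [0, 100].
#'
#' @param results list of `case_result`s, or the number of successes.
#' @param n_cases total number of cases (only when `results` is a count).
#' @return An object of class `cohort_result`: `n_cases`, `n_success`,
#'   `rate` (percent), `ci95` (low, high).
#' @export
success_rate <- function(results, n_cases = NULL) {
  if (is.numeric(results)) {
    if (is.null(n_cases)) stop("parameter error: n_cases required with a count", call. = FALSE)
    k <- results; n <- n_cases
  } else {
    if (length(results) == 0L)
      stop("parameter error: empty result list", call. = FALSE)
    k <- sum(vapply(results, function(r) isTRUE(r$success), logical(1)))
    n <- length(results)
  }
  if (n < 1L || k < 0 || k > n)
    stop("parameter error: need 0 <= n_success <= n_cases, n_cases >= 1", call. = FALSE)
  p <- k / n
  half <- stats::qnorm(0.975) * sqrt(p * (1 - p) / n)
  structure(list(n_cases = n, n_success = k, rate = 100 * p,
                 ci95 = c(low = max(0, 100 * (p - half)),
                          high = min(100, 100 * (p + half)))),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("<cohort_result> %d/%d cases, success rate %.1f%% (95%% CI %.1f-%.1f)\n",
              x$n_success, x$n_cases, x$rate, x$ci95["low"], x$ci95["high"]))
  invisible(x)
}
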