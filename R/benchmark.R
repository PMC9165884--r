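# Variant-level evaluation: binary splice-affecting classification with
# empirical optimal thresholds, exact-effect classification, and paired
# model comparison by predictive error.

#' Area under the precision-recall curve
#'
#' Step-wise interpolation of the precision-recall curve (the sum of
#' `precision * recall-increment` over distinct score thresholds, descending),
#' i.e. average precision. Tied scores are grouped. `-Inf` scores (missing
#' predictions filled as non-affecting) sort below every real score.
#'
#' This single implementation backs both model validation during training
#' and the variant benchmark.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or 0/1) ground-truth positives.
#' @return area in `[0, 1]`.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  if (n_pos == 0L || n_pos == length(labels)) {
    stop("PR-AUC undefined: ground truth has a single class")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  grp_last <- c(s[-1L] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- cumsum(l)[grp_last]
  fp <- cumsum(!l)[grp_last]
  precision <- tp / (tp + fp)
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Area under the ROC curve
#'
#' Rank statistic (Mann-Whitney) form, with midranks for ties; equivalent to
#' the trapezoidal area under the ROC curve.
#'
#' @inheritParams pr_auc
#' @return area in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("ROC-AUC undefined: ground truth has a single class")
  }
  r <- rank(scores)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Evaluate the binary splice-affecting classification task
#'
#' Scores are per-variant maxima (e.g. max over the four delta scores and
#' over overlapping genes); variants with no prediction (`NA`) are filled as
#' non-affecting — a `-Inf` surrogate that sorts below every real score, so
#' a tool legitimately scoring 0 remains distinguishable — but count against
#' coverage. The optimal threshold is the accuracy-maximising cut over all
#' candidate thresholds (midpoints between adjacent distinct finite scores
#' plus the two extremes), ties broken toward the smallest threshold; a
#' variant is called affecting when `score >= threshold`.
#'
#' @param scores named numeric vector keyed by variant id; `NA` = missing.
#' @param truth data frame with columns `variant_id` and `affects_splicing`
#'   (logical), or a list of ground-truth variants from [load_truth_csv()].
#' @return list of class `binary_eval` with `coverage`, `auc_pr`, `auc_roc`,
#'   `optimal_threshold`, `accuracy_at_optimal` and `n`.
#' @export
binary_eval <- function(scores, truth) {
  truth <- as_truth_df(truth)
  if (nrow(truth) == 0L) stop("empty ground truth")
  labels <- as.logical(truth$affects_splicing)
  if (all(labels) || !any(labels)) {
    stop("ground truth has a single class; AUCs undefined")
  }
  s <- unname(scores[match(truth$variant_id, names(scores))])
  covered <- !is.na(s)
  s[!covered] <- -Inf
  finite <- sort(unique(s[is.finite(s)]))
  if (length(finite) == 0L) finite <- 0
  candidates <- unique(c(
    finite[1L] - 1,
    if (length(finite) > 1L) (finite[-1L] + finite[-length(finite)]) / 2,
    finite[length(finite)] + 1
  ))
  acc <- vapply(candidates, function(t) mean((s >= t) == labels), numeric(1))
  best <- which(acc == max(acc))[1L]   # candidates ascending: smallest wins ties
  structure(
    list(coverage = mean(covered),
         auc_pr = pr_auc(s, labels),
         auc_roc = roc_auc(s, labels),
         optimal_threshold = candidates[best],
         accuracy_at_optimal = acc[best],
         n = length(labels)),
    class = "binary_eval"
  )
}

#' @export
print.binary_eval <- function(x, ...) {
  cat(sprintf(paste0(
    "<binary_eval> n = %d\n",
    "  coverage            %6.2f%%\n",
    "  AUC-PR              %6.2f%%\n",
    "  AUC-ROC             %6.2f%%\n",
    "  optimal threshold   %.4g\n",
    "  accuracy at optimal %6.2f%%\n"),
    x$n, 100 * x$coverage, 100 * x$auc_pr, 100 * x$auc_roc,
    x$optimal_threshold, 100 * x$accuracy_at_optimal))
  invisible(x)
}

EFFECT_CLASSES <- c("acceptor_gain", "acceptor_loss", "donor_gain", "donor_loss")

#' Evaluate the exact-effect classification task
#'
#' Restricted to ground-truth variants that carry exact effect annotations
#' (class + genomic position of the gain/loss event). For each effect class,
#' a variant counts correct when the predicted position for that class — the
#' variant position plus the delta position (DP) of the gene entry with the
#' highest delta score of that class — matches an annotated event position
#' exactly (optionally within `tolerance` bases). Classes with no variants
#' are reported `NA`.
#'
#' @param annotations data frame as returned by [read_delta_vcf()]: one row
#'   per variant x gene with columns `variant_id`, `pos`, `DS_AG`, `DS_AL`,
#'   `DS_DG`, `DS_DL`, `DP_AG`, `DP_AL`, `DP_DG`, `DP_DL`.
#' @param truth ground truth from [load_truth_csv()] (only rows with effects
#'   are used).
#' @param tolerance allowed absolute position error in bases (default 0,
#'   exact match).
#' @return list of class `exact_eval`: per-class accuracy, correct and total
#'   counts.
#' @export
exact_eval <- function(annotations, truth, tolerance = 0L) {
  truth <- as_truth_df(truth)
  truth <- truth[vapply(truth$effects, length, integer(1)) > 0L, , drop = FALSE]
  correct <- setNames(integer(4), EFFECT_CLASSES)
  total <- setNames(integer(4), EFFECT_CLASSES)
  ds_col <- c(acceptor_gain = "DS_AG", acceptor_loss = "DS_AL",
              donor_gain = "DS_DG", donor_loss = "DS_DL")
  dp_col <- c(acceptor_gain = "DP_AG", acceptor_loss = "DP_AL",
              donor_gain = "DP_DG", donor_loss = "DP_DL")
  for (i in seq_len(nrow(truth))) {
    effects <- truth$effects[[i]]
    vid <- truth$variant_id[i]
    rows <- annotations[annotations$variant_id == vid, , drop = FALSE]
    by_class <- split(vapply(effects, `[[`, numeric(1), "pos"),
                      vapply(effects, `[[`, character(1), "class"))
    for (cls in names(by_class)) {
      total[cls] <- total[cls] + 1L
      if (nrow(rows) == 0L) next
      best <- rows[which.max(rows[[ds_col[cls]]]), , drop = FALSE]
      predicted <- best$pos + best[[dp_col[cls]]]
      if (any(abs(predicted - by_class[[cls]]) <= tolerance)) {
        correct[cls] <- correct[cls] + 1L
      }
    }
  }
  accuracy <- ifelse(total > 0L, correct / total, NA_real_)
  structure(list(accuracy = accuracy, correct = correct, total = total,
                 tolerance = tolerance),
            class = "exact_eval")
}

#' @export
print.exact_eval <- function(x, ...) {
  cat("<exact_eval> per-class accuracy (correct/total):\n")
  for (cls in names(x$accuracy)) {
    cat(sprintf("  %-14s %s (%d/%d)\n", cls,
                ifelse(is.na(x$accuracy[cls]), "NA",
                       sprintf("%6.2f%%", 100 * x$accuracy[cls])),
                x$correct[cls], x$total[cls]))
  }
  invisible(x)
}

#' Compare the predictive error of two models
#'
#' The predictive error of a variant is the absolute difference between its
#' most significant prediction (max score, missing filled as 0) and the
#' ground truth (1 if affecting, else 0). Reports the fraction of variants
#' whose error changed between models and, among those, the fraction where
#' model `b` improved on model `a`.
#'
#' @param scores_a,scores_b named numeric vectors keyed by variant id.
#' @param truth ground truth (see [binary_eval()]).
#' @return list with `fraction_changed`, `fraction_improved`, and a
#'   per-variant data frame `errors`.
#' @export
compare_predictive_error <- function(scores_a, scores_b, truth) {
  truth <- as_truth_df(truth)
  label <- as.numeric(truth$affects_splicing)
  get <- function(scores) {
    s <- unname(scores[match(truth$variant_id, names(scores))])
    s[is.na(s)] <- 0
    s
  }
  ea <- abs(get(scores_a) - label)
  eb <- abs(get(scores_b) - label)
  changed <- ea != eb
  improved <- changed & (eb < ea)
  list(
    fraction_changed = mean(changed),
    fraction_improved = if (any(changed)) sum(improved) / sum(changed) else NA_real_,
    errors = data.frame(variant_id = truth$variant_id, error_a = ea,
                        error_b = eb, stringsAsFactors = FALSE)
  )
}

# -- ground truth I/O -------------------------------------------------------

variant_id <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

as_truth_df <- function(truth) {
  if (is.data.frame(truth)) {
    if (is.null(truth$variant_id)) {
      truth$variant_id <- variant_id(truth$chrom, truth$pos, truth$ref, truth$alt)
    }
    if (is.null(truth$effects)) truth$effects <- replicate(nrow(truth), list())
    return(truth)
  }
  stop("truth must be a data frame (see load_truth_csv)")
}

#' Load / write a curated ground-truth variant CSV
#'
#' Schema: `chrom`, `pos` (1-based), `ref`, `alt`, `affects_splicing`
#' (true/false), `source`, and optional `effect_class` / `effect_pos`
#' (semicolon-separated parallel lists for variants with multiple annotated
#' events; positions are 1-based genomic coordinates of the gained or lost
#' splice-site base). Duplicate genomic variants are rejected; any effect
#' annotation implies `affects_splicing`.
#'
#' @param path CSV path.
#' @return data frame with one row per variant, list-column `effects`
#'   (each element a list of `list(class=, pos=)`), and a `variant_id` key.
#' @export
load_truth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("chrom", "pos", "ref", "alt", "affects_splicing")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) stop("truth CSV missing columns: ", paste(missing, collapse = ", "))
  df$pos <- as.integer(df$pos)
  df$affects_splicing <- toupper(df$affects_splicing) %in% c("TRUE", "T", "1", "YES")
  if (is.null(df$source)) df$source <- NA_character_
  ids <- variant_id(df$chrom, df$pos, df$ref, df$alt)
  if (anyDuplicated(ids)) stop("duplicate variant in truth CSV: ", ids[duplicated(ids)][1L])
  df$variant_id <- ids
  parse_effects <- function(cls, pos) {
    if (is.na(cls) || !nzchar(cls)) return(list())
    classes <- strsplit(cls, ";", fixed = TRUE)[[1L]]
    positions <- as.numeric(strsplit(pos, ";", fixed = TRUE)[[1L]])
    if (length(classes) != length(positions)) {
      stop("effect_class / effect_pos length mismatch: ", cls)
    }
    bad <- setdiff(classes, EFFECT_CLASSES)
    if (length(bad) > 0L) stop("unknown effect class: ", bad[1L])
    unname(Map(function(c, p) list(class = c, pos = p), classes, positions))
  }
  if (!is.null(df$effect_class)) {
    df$effects <- unname(Map(parse_effects, df$effect_class, df$effect_pos))
    has_eff <- vapply(df$effects, length, integer(1)) > 0L
    if (any(has_eff & !df$affects_splicing)) {
      stop("variant with effect annotation marked non-affecting")
    }
  } else {
    df$effects <- replicate(nrow(df), list())
  }
  df
}

#' @rdname load_truth_csv
#' @param truth data frame in the layout produced by [load_truth_csv()].
#' @export
write_truth_csv <- function(truth, path) {
  eff <- truth$effects %||% replicate(nrow(truth), list())
  out <- data.frame(
    chrom = truth$chrom,
    pos = truth$pos,
    ref = truth$ref,
    alt = truth$alt,
    affects_splicing = tolower(as.character(truth$affects_splicing)),
    source = truth$source %||% "unknown",
    effect_class = vapply(eff, function(e) {
      paste(vapply(e, `[[`, character(1), "class"), collapse = ";")
    }, character(1)),
    effect_pos = vapply(eff, function(e) {
      paste(vapply(e, `[[`, numeric(1), "pos"), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
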