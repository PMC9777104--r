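# Evaluation: pixel confusion counts, Dice / precision / recall,
# connected-component labeling, the aggregated Jaccard index (AJI), and
# dataset-level scoring with mean and sample SD across images.

#' Pixel confusion counts between two binary masks
#'
#' @param gt,pred Binary masks of equal shape (any nonzero value counts as
#'   foreground).
#' @return List with `tp`, `fp`, `fn`, `tn`; they sum to the pixel count.
#' @export
confusion_counts <- function(gt, pred) {
  if (!all(dim_or_len(gt) == dim_or_len(pred))) stop("mask shapes differ")
  g <- gt > 0; p <- pred > 0
  list(tp = sum(g & p), fp = sum(!g & p), fn = sum(g & !p), tn = sum(!g & !p))
}

#' Dice coefficient from confusion counts
#'
#' `2 TP / (2 TP + FP + FN)`; when both masks are empty the score is 1.
#'
#' @param c Counts from [confusion_counts()].
#' @return Fraction in `[0, 1]`.
#' @export
dice_score <- function(c) {
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(1)
  2 * c$tp / den
}

#' Precision from confusion counts
#'
#' `TP / (TP + FP)`; reported as 1 (with a warning) when no pixels were
#' predicted positive.
#'
#' @inheritParams dice_score
#' @return Fraction in `[0, 1]`.
#' @export
precision_score <- function(c) {
  den <- c$tp + c$fp
  if (den == 0) {
    warning("precision undefined on an empty prediction; reporting 1")
    return(1)
  }
  c$tp / den
}

#' Recall from confusion counts
#'
#' `TP / (TP + FN)`; reported as 1 (with a warning) when the ground truth
#' is empty.
#'
#' @inheritParams dice_score
#' @return Fraction in `[0, 1]`.
#' @export
recall_score <- function(c) {
  den <- c$tp + c$fn
  if (den == 0) {
    warning("recall undefined on an empty ground truth; reporting 1")
    return(1)
  }
  c$tp / den
}

#' Label connected foreground components
#'
#' Maximal connected components of the nonzero pixels, labeled 1..k in
#' scanline (row-by-row) discovery order.
#'
#' @param mask Binary matrix.
#' @param connectivity 4 or 8.
#' @return Integer label matrix.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  m <- mask
  storage.mode(m) <- "integer"
  label_components_cpp(m, as.integer(connectivity))
}

#' Aggregated Jaccard index between instance masks
#'
#' For each ground-truth instance in ascending label order, the unused
#' predicted component with maximal pairwise Jaccard is matched (ties go
#' to the smaller predicted label); its intersection and union accumulate
#' into numerator and denominator. Ground-truth instances with no
#' available overlapping prediction contribute their size to the
#' denominator, as do all predicted components left unmatched.
#'
#' @param gt,pred Integer instance masks of equal shape (0 = background;
#'   labels need not be consecutive).
#' @return Fraction in `[0, 1]` (1 when both masks are empty).
#' @export
aji <- function(gt, pred) {
  if (!all(dim(gt) == dim(pred))) stop("mask shapes differ")
  gv <- as.vector(gt); pv <- as.vector(pred)
  gt_labels <- sort(unique(gv[gv > 0]))
  pred_labels <- sort(unique(pv[pv > 0]))
  gt_sizes <- tabulate_labels(gv, gt_labels)
  pred_sizes <- tabulate_labels(pv, pred_labels)
  if (length(gt_labels) == 0L && length(pred_labels) == 0L) return(1)
  both <- gv > 0 & pv > 0
  ov <- if (any(both)) {
    as.data.frame(table(g = gv[both], p = pv[both]), stringsAsFactors = FALSE)
  } else {
    data.frame(g = character(0), p = character(0), Freq = integer(0))
  }
  ov <- ov[ov$Freq > 0, ]
  used <- logical(length(pred_labels))
  names(used) <- as.character(pred_labels)
  num <- 0; den <- 0
  for (gl in gt_labels) {
    cand <- ov[ov$g == as.character(gl), ]
    cand <- cand[!used[cand$p], ]
    if (nrow(cand) == 0L) {
      den <- den + gt_sizes[[as.character(gl)]]
      next
    }
    gs <- gt_sizes[[as.character(gl)]]
    inter <- cand$Freq
    un <- gs + pred_sizes[cand$p] - inter
    jac <- inter / un
    best <- which(jac == max(jac))
    if (length(best) > 1L) best <- best[order(as.integer(cand$p[best]))[1]]
    num <- num + inter[best]
    den <- den + un[best]
    used[cand$p[best]] <- TRUE
  }
  den <- den + sum(pred_sizes[!used])
  if (den == 0) return(1)
  unname(num / den)
}

tabulate_labels <- function(v, labels) {
  out <- as.numeric(table(factor(v[v > 0], levels = labels)))
  names(out) <- as.character(labels)
  out
}

#' Evaluate a directory of predictions against ground truth
#'
#' Files are matched by base name (extensions may differ). Dice, precision
#' and recall are computed on binarized masks; AJI uses the ground-truth
#' instance labels (or its connected components if binary) against the
#' connected components of the prediction.
#'
#' @param pred_dir Directory of predicted masks (PNG or TIFF).
#' @param gt_dir Directory of ground-truth masks.
#' @param connectivity Component connectivity for binary masks.
#' @param out_csv Optional path for the per-image + summary CSV.
#' @return A `seg_scores` list: `per_image` (data frame), `summary`
#'   (mean and sample SD per metric).
#' @export
evaluate_dataset <- function(pred_dir, gt_dir, connectivity = 8L,
                             out_csv = NULL) {
  list_masks <- function(d) {
    f <- list.files(d, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
    stats::setNames(file.path(d, f), tools::file_path_sans_ext(f))
  }
  preds <- list_masks(pred_dir)
  gts <- list_masks(gt_dir)
  if (length(preds) == 0L) stop("no prediction masks found in ", pred_dir)
  if (length(gts) == 0L) stop("no ground-truth masks found in ", gt_dir)
  unmatched <- c(setdiff(names(preds), names(gts)), setdiff(names(gts), names(preds)))
  if (length(unmatched)) {
    stop("unmatched mask filenames: ", paste(sort(unique(unmatched)), collapse = ", "))
  }
  nm <- sort(names(preds))
  rows <- lapply(nm, function(n) {
    pred <- load_mask(preds[[n]])
    gt <- load_mask(gts[[n]])
    cc <- confusion_counts(gt, pred)
    gt_inst <- if (max(gt) > 1L) gt else label_components(gt, connectivity)
    pred_inst <- if (max(pred) > 1L) pred else label_components(pred, connectivity)
    data.frame(image = n, dice = dice_score(cc), aji = aji(gt_inst, pred_inst),
               precision = precision_score(cc), recall = recall_score(cc))
  })
  per_image <- do.call(rbind, rows)
  metrics <- c("dice", "aji", "precision", "recall")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_image[[m]]), numeric(1)),
    sd = vapply(metrics, function(m) {
      if (nrow(per_image) > 1L) stats::sd(per_image[[m]]) else 0
    }, numeric(1))
  )
  if (!is.null(out_csv)) {
    srow <- data.frame(image = "summary", t(stats::setNames(
      sprintf("%.4f±%.4f", summary$mean, summary$sd), metrics)))
    out <- rbind(
      data.frame(image = per_image$image,
                 lapply(per_image[metrics], function(x) sprintf("%.6f", x))),
      srow)
    utils::write.csv(out, out_csv, row.names = FALSE)
  }
  structure(list(per_image = per_image, summary = summary), class = "seg_scores")
}
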