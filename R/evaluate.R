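# Dice reporting per class, whole-ureter union scoring, and the fivefold
# cross-validation harness. Reports mirror the published table layout:
# rows Avg / Split-1..5, columns avg | kidney | total + subclass ureters |
# urinary bladder. The "avg" column averages the three top-level classes
# (kidney, total ureter, urinary bladder).

#' Score one predicted case against ground truth
#'
#' Per-subclass Dice between the prediction's binary mask for a class and
#' that class's (possibly overlapping) ground-truth mask; "ureter_total"
#' compares the unions of the three subclasses. Classes empty in both
#' prediction and ground truth score 1.
#'
#' @param pred integer label volume (0 background, class index 1..5 in
#'   [uroseg_classes()] order) on the ground-truth grid.
#' @param gt a [mask_set()].
#' @param avg_over `"three"` averages kidney / total ureter / bladder (the
#'   reported layout); `"five"` averages all subclasses.
#' @return named list of Dice values: one per class, `ureter_total`, `avg`.
#' @export
score_case <- function(pred, gt, avg_over = c("three", "five")) {
  avg_over <- match.arg(avg_over)
  check_same_grid(pred, gt$masks[[1]])
  classes <- uroseg_classes()
  scores <- list()
  for (ci in seq_along(classes)) {
    nm <- classes[ci]
    scores[[nm]] <- dice_coefficient(pred == ci, gt$masks[[nm]])
  }
  uc <- ureter_classes()
  pred_ureter <- pred %in% match(uc, classes)
  dim(pred_ureter) <- dim(pred)
  gt_ureter <- Reduce(`|`, gt$masks[uc])
  scores$ureter_total <- dice_coefficient(pred_ureter, gt_ureter)
  scores$avg <- if (avg_over == "three") {
    mean(c(scores$kidney, scores$ureter_total, scores$urinary_bladder))
  } else {
    mean(unlist(scores[classes]))
  }
  scores
}

#' Assign cases to cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment: validation sets are
#' pairwise disjoint, jointly cover all cases, and differ in size by at
#' most one (573 cases over 5 folds gives validation sizes
#' 115/115/115/114/114, i.e. an 8:2 train:validation split per fold).
#'
#' @param case_ids character or integer vector of case identifiers.
#' @param n_folds number of folds (default 5).
#' @param seed shuffle seed.
#' @return a `fold_plan`: data.frame (case_id, fold) with `n_folds` attr.
#' @export
make_folds <- function(case_ids, n_folds = 5L, seed = 1L) {
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (length(case_ids) < n_folds) {
    stop("fewer cases than folds", call. = FALSE)
  }
  set.seed(seed)
  shuffled <- sample(case_ids)
  plan <- data.frame(case_id = shuffled,
                     fold = rep_len(seq_len(n_folds), length(case_ids)),
                     stringsAsFactors = FALSE)
  plan <- plan[order(match(plan$case_id, case_ids)), ]
  rownames(plan) <- NULL
  attr(plan, "n_folds") <- as.integer(n_folds)
  class(plan) <- c("fold_plan", "data.frame")
  plan
}

#' Per-fold Dice report
#'
#' @param fold_id fold number.
#' @param per_case data.frame: one row per case with columns `case_id` plus
#'   one Dice column per reported class.
#' @return a `dice_report` with per-class mean and sd.
#' @export
dice_report <- function(fold_id, per_case) {
  num_cols <- setdiff(names(per_case), "case_id")
  mean_sd <- lapply(num_cols, function(cn) {
    c(mean = mean(per_case[[cn]]), sd = stats::sd(per_case[[cn]]))
  })
  names(mean_sd) <- num_cols
  structure(list(fold_id = fold_id, per_case = per_case,
                 per_class_mean_sd = mean_sd),
            class = "dice_report")
}

report_columns <- function() {
  c("avg", "kidney", "ureter_total", "proximal_ureter", "middle_ureter",
    "distal_ureter", "urinary_bladder")
}

#' Summarise cross-validation fold reports into the published table layout
#'
#' @param reports list of `dice_report`s (one per fold).
#' @return data.frame with rows `Avg`, `Split-1` ... and the Dice columns of
#'   [report_columns()]; the `Avg` row is the column-wise mean of the fold
#'   rows.
#' @export
summarize_cv <- function(reports) {
  cols <- report_columns()
  fold_rows <- lapply(reports, function(r) {
    vals <- vapply(cols, function(cn) r$per_class_mean_sd[[cn]][["mean"]],
                   numeric(1))
    as.data.frame(as.list(vals))
  })
  tbl <- do.call(rbind, fold_rows)
  avg_row <- as.data.frame(as.list(colMeans(tbl)))
  out <- rbind(avg_row, tbl)
  out <- cbind(data.frame(split = c("Avg", paste0("Split-",
                                                  seq_along(reports)))),
               out)
  rownames(out) <- NULL
  out
}

#' Fivefold cross-validation of the stage-2 segmentation
#'
#' For each fold: trains a fresh model on the training cases, runs the full
#' stage-2 path on each validation case (oracle-ROI box from ground-truth
#' kidney/bladder, crop, resample, sliding-window predict, post-process,
#' restore), and scores Dice in the original image space. The best fold is
#' the one with the highest average Dice.
#'
#' @param cases named list of cases (each with `volume` in HU and `masks`);
#'   names are the case ids.
#' @param model_cfg a [model_config()] with `n_classes = 5`.
#' @param train_cfg a [train_config()].
#' @param plan a [make_folds()] plan over `names(cases)`.
#' @param aug an [augment_config()] or NULL.
#' @param inplane_mm stage-2 working resolution.
#' @param trainer function `(model, prepared_cases, train_cfg, aug) -> model`;
#'   the default trains with [train()]. Injectable for harness tests.
#' @param summary_csv optional path for the summary table CSV.
#' @return list with `reports`, `summary` (data.frame), `best_fold`.
#' @export
cross_validate <- function(cases, model_cfg, train_cfg = train_config(),
                           plan = make_folds(names(cases)),
                           aug = augment_config(), inplane_mm = 0.7,
                           trainer = NULL, summary_csv = NULL) {
  n_folds <- attr(plan, "n_folds")
  if (is.null(trainer)) {
    trainer <- function(model, prepared, cfg, aug) {
      train(model, prepared, cfg, aug)$model
    }
  }
  reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    val_ids <- plan$case_id[plan$fold == f]
    train_ids <- plan$case_id[plan$fold != f]
    if (length(val_ids) == 0L) {
      stop(sprintf("fold %d has an empty validation set", f), call. = FALSE)
    }
    prepared <- lapply(cases[train_ids], function(cs) {
      coarse <- mask_set(cs$masks$masks[c("kidney", "urinary_bladder")])
      box <- derive_roi_box(coarse, cs$volume)
      prepare_case(cs$volume, cs$masks, box, inplane_mm = inplane_mm)
    })
    fold_cfg <- train_cfg
    fold_cfg$seed <- train_cfg$seed + f
    model <- build_model(model_cfg, seed = fold_cfg$seed)
    model <- trainer(model, prepared, fold_cfg, aug)

    rows <- lapply(val_ids, function(id) {
      cs <- cases[[id]]
      seg <- segment_case(cs$volume, model, coarse_model = NULL,
                          gt_masks = cs$masks, inplane_mm = inplane_mm,
                          k = fold_cfg$k)
      sc <- score_case(seg$labels, cs$masks)
      data.frame(case_id = id, as.data.frame(sc[report_columns()]))
    })
    reports[[f]] <- dice_report(f, do.call(rbind, rows))
  }
  summary <- summarize_cv(reports)
  fold_avgs <- summary$avg[-1]
  best_fold <- which.max(fold_avgs)
  if (!is.null(summary_csv)) {
    utils::write.csv(summary, summary_csv, row.names = FALSE)
  }
  list(reports = reports, summary = summary, best_fold = best_fold)
}
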