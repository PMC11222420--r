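# Stage-2 training mechanics: per-epoch random non-overlapping window
# sampling from each ROI slice's CCA, optional augmentation, deep-supervision
# loss, Adam. Single-threaded and fully seeded: identical seeds reproduce
# identical loss logs.

#' Training configuration
#'
#' @param max_points_per_slice maximum non-overlapping window centres drawn
#'   per slice per epoch (default 10).
#' @param epochs passes over the cohort.
#' @param batch_size windows per optimiser step.
#' @param optimizer only `"adam"`.
#' @param lr learning rate.
#' @param k training window side length.
#' @param slice_stride train on every `slice_stride`-th axial slice
#'   (desk-scale runs subsample slices; 1 = all slices).
#' @param sample_mode `"all"` samples every ROI slice uniformly;
#'   `"foreground"` restricts to slices containing any foreground class.
#' @param seed RNG seed for sampling, augmentation and shuffling.
#' @return a `train_config` list.
#' @export
train_config <- function(max_points_per_slice = 10L, epochs = 1L,
                         batch_size = 16L, optimizer = "adam", lr = 1e-4,
                         k = 128L, slice_stride = 1L,
                         sample_mode = c("all", "foreground"), seed = 1L) {
  sample_mode <- match.arg(sample_mode)
  stopifnot(max_points_per_slice >= 1L)
  if (optimizer != "adam") stop("only the adam optimizer is provided", call. = FALSE)
  structure(list(max_points_per_slice = as.integer(max_points_per_slice),
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 optimizer = optimizer, lr = lr, k = as.integer(k),
                 slice_stride = as.integer(slice_stride),
                 sample_mode = sample_mode, seed = as.integer(seed)),
            class = "train_config")
}

#' Prepare one case for stage-2 training/inference
#'
#' Crops to the ROI box, resamples in-plane to the working resolution
#' (0.7 mm; the slice axis keeps its native spacing), and normalises
#' intensities.
#'
#' @param vol case [ct_volume()] in HU.
#' @param masks case [mask_set()] (NULL for inference-only preparation).
#' @param box a [roi_box()].
#' @param inplane_mm target in-plane pixel size.
#' @return list with normalised `volume` and nearest-resampled `masks`.
#' @export
prepare_case <- function(vol, masks, box, inplane_mm = 0.7) {
  cr <- crop_to_box(vol, masks, box)
  target <- c(cr$volume$spacing[1], inplane_mm, inplane_mm)
  v <- resample(cr$volume, target, interp = "linear")
  v <- normalize_hu(v)
  m <- NULL
  if (!is.null(cr$masks)) {
    m <- resample_mask_set(cr$masks, cr$volume, target)
  }
  list(volume = v, masks = m)
}

# pad slice + masks up to at least k x k (centre pad, background fill)
pad_slice_to_k <- function(img, mlist, k) {
  d <- dim(img)
  if (d[1] >= k && d[2] >= k) return(list(img = img, masks = mlist))
  size <- pmax(d, k)
  img2 <- pad_or_crop_to(img, size, fill = 0)
  attr(img2, "offset") <- NULL
  m2 <- lapply(mlist, function(m) {
    mm <- pad_or_crop_to(m, size, fill = 0)
    attr(mm, "offset") <- NULL
    storage.mode(mm) <- "integer"
    mm
  })
  list(img = img2, masks = m2)
}

#' One optimiser step on a batch of windows
#'
#' @param model a `munet`.
#' @param opt an Adam state from [adam_state()].
#' @param xbatch array (k, k, 1, B), normalised intensities.
#' @param ybatch array (k, k, N_c, B), binary targets.
#' @return the scalar deep-supervision loss before the step.
#' @export
train_step <- function(model, opt, xbatch, ybatch) {
  out <- munet_forward(model, xbatch, training = TRUE)
  dsl <- deep_supervision_loss(out, ybatch, with_grad = TRUE)
  if (!is.finite(dsl$total)) {
    dump <- file.path(tempdir(), sprintf("uroseg-nonfinite-%d.rds",
                                         as.integer(Sys.time())))
    saveRDS(list(xbatch = xbatch, ybatch = ybatch), dump)
    stop(sprintf("non-finite training loss; offending batch dumped to %s", dump),
         call. = FALSE)
  }
  munet_backward(model, dsl$grads)
  adam_step(opt)
  dsl$total
}

# gather the (k x k) training windows of one slice
slice_windows <- function(img, mlist, centres, k) {
  xs <- vector("list", nrow(centres))
  ys <- vector("list", nrow(centres))
  for (i in seq_len(nrow(centres))) {
    ex <- window_extent(centres[i, 1], k)  # x (columns)
    ey <- window_extent(centres[i, 2], k)  # y (rows)
    rows <- (ey[1] + 1):ey[2]
    cols <- (ex[1] + 1):ex[2]
    xs[[i]] <- img[rows, cols]
    ys[[i]] <- lapply(mlist, function(m) m[rows, cols])
  }
  list(x = xs, y = ys)
}

#' Train a model on prepared ROI cases
#'
#' Per epoch, per retained axial slice: sample up to
#' `max_points_per_slice` non-overlapping window centres from the CCA, crop
#' the k x k image/mask windows, augment, and take an Adam step on the
#' deep-supervision loss once `batch_size` windows have accumulated.
#'
#' @param model a `munet` whose N_c matches the mask classes.
#' @param cases list of prepared cases from [prepare_case()] (each with
#'   normalised `volume` and `masks`).
#' @param cfg a [train_config()].
#' @param aug an [augment_config()] or NULL to disable augmentation.
#' @param checkpoint_path optional path: the trained model and configs are
#'   saved there (RDS) after the final epoch.
#' @param refresh_bn recompute batch-norm running statistics from recent
#'   training batches after the final epoch (see [refresh_bn_stats()]);
#'   recommended for short desk-scale trainings.
#' @return list with `model`, `loss_log` (data.frame epoch, step, loss), and
#'   `opt`.
#' @export
train <- function(model, cases, cfg = train_config(), aug = augment_config(),
                  checkpoint_path = NULL, refresh_bn = TRUE) {
  set.seed(cfg$seed)
  opt <- adam_state(model_param_modules(model), lr = cfg$lr)
  class_names <- model_class_names(cases)
  k <- cfg$k
  log_rows <- list()
  step <- 0L
  pending_x <- list(); pending_y <- list()
  recent_batches <- list()

  flush_batch <- function() {
    if (length(pending_x) == 0L) return(invisible(NULL))
    B <- length(pending_x)
    xb <- array(0, dim = c(k, k, 1L, B))
    yb <- array(0, dim = c(k, k, length(class_names), B))
    for (i in seq_len(B)) {
      xb[, , 1L, i] <- pending_x[[i]]
      for (ci in seq_along(class_names)) {
        yb[, , ci, i] <- pending_y[[i]][[ci]]
      }
    }
    loss <- train_step(model, opt, xb, yb)
    recent_batches[[1L + (step %% 8L)]] <<- xb
    step <<- step + 1L
    log_rows[[length(log_rows) + 1L]] <<- data.frame(epoch = epoch, step = step,
                                                     loss = loss)
    pending_x <<- list(); pending_y <<- list()
    invisible(NULL)
  }

  for (epoch in seq_len(cfg$epochs)) {
    for (case in cases) {
      vol <- case$volume
      masks <- case$masks
      nz <- dim(vol$data)[1]
      slices <- seq(1L, nz, by = cfg$slice_stride)
      if (cfg$sample_mode == "foreground") {
        fg <- Reduce(`+`, lapply(masks$masks, function(m) {
          apply(m, 1, sum)
        }))
        slices <- slices[fg[slices] > 0]
        if (length(slices) == 0L) next
      }
      for (si in slices) {
        img <- vol$data[si, , ]
        mlist <- lapply(masks$masks, function(m) m[si, , ])
        padded <- pad_slice_to_k(img, mlist, k)
        geom <- window_geometry(nrow(padded$img), ncol(padded$img), k = k)
        centres <- sample_window_centres(geom, cfg$max_points_per_slice)
        wins <- slice_windows(padded$img, padded$masks, centres, k)
        for (i in seq_along(wins$x)) {
          wi <- wins$x[[i]]; my <- wins$y[[i]]
          if (!is.null(aug)) {
            a <- augment(wi, my, aug)
            wi <- a$image; my <- a$masks
          }
          pending_x[[length(pending_x) + 1L]] <- wi
          pending_y[[length(pending_y) + 1L]] <- my
          if (length(pending_x) >= cfg$batch_size) flush_batch()
        }
      }
    }
    flush_batch()
  }
  loss_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(epoch = integer(0), step = integer(0), loss = numeric(0))
  if (refresh_bn) refresh_bn_stats(model, recent_batches)
  if (!is.null(checkpoint_path)) {
    save_checkpoint(model, checkpoint_path, train_cfg = cfg, augment_cfg = aug)
  }
  list(model = model, loss_log = loss_log, opt = opt)
}

model_class_names <- function(cases) {
  cases[[1]]$masks$class_names
}

#' Recompute batch-norm running statistics from data
#'
#' After short desk-scale trainings the exponentially averaged batch-norm
#' statistics can lag far behind the trained weights, making inference-mode
#' forward passes inconsistent with training. This pass resets the running
#' statistics and replaces them with the equally weighted mean of the batch
#' statistics over the supplied batches (the usual post-training refresh).
#'
#' @param model a `munet`.
#' @param batches list of input arrays (k, k, 1, B).
#' @return the model, invisibly.
#' @export
refresh_bn_stats <- function(model, batches) {
  mods <- model_param_modules(model)
  bns <- Filter(function(m) m$type == "bn", mods)
  if (length(bns) == 0L || length(batches) == 0L) return(invisible(model))
  saved_momentum <- vapply(bns, function(m) m$momentum, numeric(1))
  for (m in bns) {
    m$state$running_mean[] <- 0
    m$state$running_var[] <- 0
  }
  for (i in seq_along(batches)) {
    for (m in bns) m$momentum <- 1 / i  # cumulative mean of batch stats
    munet_forward(model, batches[[i]], training = TRUE)
  }
  for (j in seq_along(bns)) bns[[j]]$momentum <- saved_momentum[j]
  invisible(model)
}

# ---- checkpointing ----

serialize_model <- function(model) {
  mods <- model_param_modules(model)
  list(cfg = model$cfg,
       params = lapply(mods, function(m) m$params),
       state = lapply(mods, function(m) m$state))
}

restore_model <- function(ser) {
  model <- build_model(ser$cfg)
  mods <- model_param_modules(model)
  stopifnot(length(mods) == length(ser$params))
  for (i in seq_along(mods)) {
    mods[[i]]$params <- ser$params[[i]]
    mods[[i]]$state <- ser$state[[i]]
  }
  model
}

#' Save a model checkpoint (weights + config, RDS)
#' @param model a `munet`.
#' @param path output file.
#' @param train_cfg,augment_cfg configs embedded for provenance.
#' @export
save_checkpoint <- function(model, path, train_cfg = NULL, augment_cfg = NULL) {
  saveRDS(list(model = serialize_model(model), train_cfg = train_cfg,
               augment_cfg = augment_cfg, package_version = "uroseg 0.1.0"),
          path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return list with `model`, `train_cfg`, `augment_cfg`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  list(model = restore_model(ck$model), train_cfg = ck$train_cfg,
       augment_cfg = ck$augment_cfg)
}
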