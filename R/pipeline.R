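# End-to-end pipeline: load (or take in-memory) two classes of images,
# fit each image's lag model, split train/test, train the discriminant on
# the training parameters, classify the test images, fit the logistic
# probability map, compute baselines, and write a reproducible report.
#
# The discriminant features are always the one-lag coefficients (k = 3);
# the per-image significance search up to `max_lag` is run and recorded,
# mirroring the empirical finding that no image needs more than one lag.

#' Pipeline run configuration
#'
#' @param class_a,class_b the two classes: either directory paths holding
#'   image files or in-memory lists of [grayscale_image]s.
#' @param label_a,label_b class labels. Class B plays the "positive" role:
#'   the discriminant is oriented so it projects higher and the logistic
#'   probability is the probability of membership in class B.
#' @param train_count training images drawn per class (default 80 of 100).
#' @param seed seed for the random train/test split (and nothing else).
#' @param alpha_t,alpha_chi,max_lag significance-search settings, see
#'   [select_lag_order].
#' @param r_squared goodness-of-fit flavour, see [fit_ols].
#' @param decision_rule `"midpoint"` or `"gaussian"`, see [fld_classify].
#' @param lr_on fit the logistic map on `"test"` projections (default,
#'   matching the construction where classified test projections feed the
#'   regression) or on `"train"` projections.
#' @param spreading_threshold optional intensity threshold for the
#'   spreading-area baseline; omitted if `NULL` (there is no defensible
#'   default, so the user must choose one).
#' @param output_dir optional directory for [write_report].
#' @return A list of class `run_config`.
#' @export
run_config <- function(class_a, class_b, label_a = "A", label_b = "B",
                       train_count = 80, seed = 1L,
                       alpha_t = 0.05, alpha_chi = 0.01, max_lag = 3,
                       r_squared = "uncentered",
                       decision_rule = c("midpoint", "gaussian"),
                       lr_on = c("test", "train"),
                       spreading_threshold = NULL, output_dir = NULL) {
  structure(
    list(class_a = class_a, class_b = class_b,
         label_a = label_a, label_b = label_b,
         train_count = as.integer(train_count), seed = as.integer(seed),
         alpha_t = alpha_t, alpha_chi = alpha_chi,
         max_lag = as.integer(max_lag), r_squared = r_squared,
         decision_rule = match.arg(decision_rule),
         lr_on = match.arg(lr_on),
         spreading_threshold = spreading_threshold,
         output_dir = output_dir),
    class = "run_config"
  )
}

#' Load all images of a class from a directory
#'
#' Reads every `.tif`, `.tiff`, `.pgm` and `.csv` file in deterministic
#' filename-sorted order. An optional `metadata.json` in the directory may
#' supply `{"pixel_size_nm": ...}`.
#'
#' @param dir directory path.
#' @param label class label attached to the result.
#' @return List with `images` (named list of [grayscale_image]), `label`,
#'   `ids` (filenames).
#' @export
load_class_images <- function(dir, label) {
  if (!dir.exists(dir)) stop("class directory not found: ", dir, call. = FALSE)
  files <- list.files(dir, pattern = "\\.(tif|tiff|pgm|csv)$",
                      ignore.case = TRUE)
  files <- sort(files, method = "radix")
  if (length(files) == 0L) {
    stop("no readable image files (.tif/.tiff/.pgm/.csv) in ", dir,
         call. = FALSE)
  }
  px_nm <- 73
  meta_path <- file.path(dir, "metadata.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$pixel_size_nm)) px_nm <- as.numeric(meta$pixel_size_nm)
  }
  images <- lapply(files, function(f) {
    tryCatch(read_image(file.path(dir, f), pixel_size_nm = px_nm),
             error = function(e) {
               stop("failed to read image '", f, "' in ", dir, ": ",
                    conditionMessage(e), call. = FALSE)
             })
  })
  names(images) <- files
  list(images = images, label = label, ids = files)
}

#' Reproducible train/test split
#'
#' Uniform random subset of `train_count` ids without replacement; the
#' complement is the test set. Deterministic given the seed.
#'
#' @param ids character vector of image ids.
#' @param train_count number of training ids, `0 < train_count < length(ids)`.
#' @param seed split seed.
#' @return List with `train` and `test` id vectors.
#' @export
split_train_test <- function(ids, train_count, seed) {
  n <- length(ids)
  if (train_count < 1L) stop("`train_count` must be at least 1", call. = FALSE)
  if (train_count >= n) {
    stop(sprintf("`train_count` (%d) must be smaller than the class size (%d)",
                 train_count, n), call. = FALSE)
  }
  train <- with_seed(seed, sort(sample.int(n, train_count)))
  list(train = ids[train], test = ids[-train])
}

normalize_class <- function(x, label) {
  if (is.character(x) && length(x) == 1L) return(load_class_images(x, label))
  if (is.list(x)) {
    images <- lapply(x, as_grayscale_image)
    ids <- names(images)
    if (is.null(ids) || any(!nzchar(ids))) {
      ids <- sprintf("%s_%03d", label, seq_along(images))
      names(images) <- ids
    }
    return(list(images = images, label = label, ids = ids))
  }
  stop("a class must be a directory path or a list of images", call. = FALSE)
}

fit_record <- function(id, label, fit1, selected) {
  rec <- data.frame(
    file = id, label = label,
    lag_order = fit1$lag_order, selected_lag = selected$lag_order,
    n_samples = fit1$n_samples,
    r_squared = fit1$r_squared,
    significant = selected$significant,
    wald_stat = fit1$wald_stat, wald_p = fit1$wald_p,
    stringsAsFactors = FALSE
  )
  for (h in seq_along(fit1$beta)) {
    nm <- names(fit1$beta)[h]
    rec[[paste0("beta_", nm)]] <- fit1$beta[h]
    rec[[paste0("se_", nm)]] <- fit1$se[h]
    rec[[paste0("t_", nm)]] <- fit1$t_stats[h]
    rec[[paste0("p_", nm)]] <- fit1$p_values[h]
  }
  rec
}

baseline_record <- function(id, label, img, spreading_threshold) {
  s <- signal_lognormal(img)
  rec <- data.frame(
    file = id, label = label,
    mean_intensity = s$mean_intensity, total_intensity = s$total_intensity,
    background_median = s$background_median,
    signal_threshold = s$signal_threshold, n_signal = s$n_signal,
    lognormal_mu = s$lognormal_mu, lognormal_sigma = s$lognormal_sigma,
    insufficient_signal = s$insufficient_signal,
    stringsAsFactors = FALSE
  )
  if (!is.null(spreading_threshold)) {
    a <- spreading_area(img, spreading_threshold)
    rec$spreading_threshold <- a$threshold
    rec$spreading_pixels <- a$pixel_count
    rec$spreading_area_um2 <- a$area_um2
  }
  rec
}

#' Run the full discrimination pipeline
#'
#' Fits every image's lag model, splits each class into train/test with
#' the configured seed, trains the Fisher discriminant on the training
#' one-lag coefficients, classifies the test projections, fits the
#' logistic probability map, and computes per-image baselines plus a
#' Kullback comparison of the two test projection sets.
#'
#' @param config a [run_config].
#' @return A list of class `run_report` with elements `fits`,
#'   `baselines` (data frames), `fld` ([fld_fit] model), `split`,
#'   `projections`, `classification`, `lr` model, `probabilities`,
#'   `kullback`, `config`, `timings`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]

  t0 <- tic()
  cls <- list(A = normalize_class(config$class_a, config$label_a),
              B = normalize_class(config$class_b, config$label_b))
  timings["load_s"] <- tic() - t0

  t0 <- tic()
  fits <- list(); baselines <- list(); params <- list()
  for (side in c("A", "B")) {
    c_ <- cls[[side]]
    k_rows <- lapply(seq_along(c_$images), function(r) {
      img <- c_$images[[r]]
      fit1 <- fit_ols(build_lagged_design(img, lag_structure(1)),
                      r_squared = config$r_squared)
      fit1$significant <- all(fit1$p_values < config$alpha_t)
      selected <- if (config$max_lag > 1L) {
        select_lag_order(img, alpha_t = config$alpha_t,
                         alpha_chi = config$alpha_chi,
                         max_order = config$max_lag,
                         r_squared = config$r_squared)
      } else fit1
      list(fit = fit_record(c_$ids[r], c_$label, fit1, selected),
           base = baseline_record(c_$ids[r], c_$label, img,
                                  config$spreading_threshold),
           beta = fit1$beta)
    })
    fits[[side]] <- do.call(rbind, lapply(k_rows, `[[`, "fit"))
    baselines[[side]] <- do.call(rbind, lapply(k_rows, `[[`, "base"))
    pm <- do.call(rbind, lapply(k_rows, `[[`, "beta"))
    rownames(pm) <- c_$ids
    params[[side]] <- pm
  }
  timings["fit_s"] <- tic() - t0

  t0 <- tic()
  split <- list(
    A = split_train_test(cls$A$ids, config$train_count, config$seed),
    B = split_train_test(cls$B$ids, config$train_count, config$seed + 1L)
  )
  fld <- fld_fit(
    class_parameter_matrix(params$A[split$A$train, , drop = FALSE],
                           cls$A$label, split$A$train),
    class_parameter_matrix(params$B[split$B$train, , drop = FALSE],
                           cls$B$label, split$B$train)
  )
  proj_tab <- do.call(rbind, lapply(c("A", "B"), function(side) {
    do.call(rbind, lapply(c("train", "test"), function(set) {
      ids <- split[[side]][[set]]
      data.frame(
        file = ids, label = cls[[side]]$label, set = set,
        projection = fld_project(fld, params[[side]][ids, , drop = FALSE]),
        stringsAsFactors = FALSE
      )
    }))
  }))
  cl <- fld_classify(fld, proj_tab$projection, rule = config$decision_rule)
  proj_tab$predicted <- cl$labels
  test_rows <- proj_tab$set == "test"
  classification <- fld_classify(
    fld, proj_tab$projection[test_rows],
    true_labels = proj_tab$label[test_rows], rule = config$decision_rule
  )
  timings["fld_s"] <- tic() - t0

  t0 <- tic()
  lr_rows <- if (config$lr_on == "test") test_rows else !test_rows
  lr <- logistic_fit(proj_tab$projection[lr_rows],
                     as.integer(proj_tab$label[lr_rows] == cls$B$label))
  probabilities <- data.frame(
    file = proj_tab$file[test_rows],
    label = proj_tab$label[test_rows],
    projection = proj_tab$projection[test_rows],
    probability = logistic_predict(lr, proj_tab$projection[test_rows]),
    stringsAsFactors = FALSE
  )
  pa <- proj_tab$projection[test_rows & proj_tab$label == cls$A$label]
  pb <- proj_tab$projection[test_rows & proj_tab$label == cls$B$label]
  kull <- if (length(pa) >= 5L && length(pb) >= 5L) {
    kullback_mdi(pa, pb)
  } else {
    list(statistic = NA_real_, p_value = NA_real_, divergence = NA_real_,
         reject_05 = NA, n_A = length(pa), n_B = length(pb),
         note = "test sets too small (< 5 per class)")
  }
  timings["lr_s"] <- tic() - t0

  report <- structure(
    list(fits = rbind(fits$A, fits$B),
         baselines = rbind(baselines$A, baselines$B),
         fld = fld, split = split, projections = proj_tab,
         classification = classification, lr = lr,
         probabilities = probabilities, kullback = kull,
         config = config, timings = as.list(timings)),
    class = "run_report"
  )
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s vs %s: %d images\n",
              x$config$label_a, x$config$label_b, nrow(x$fits)))
  cat(sprintf("test accuracy %.3f (training %.3f)\n",
              x$classification$accuracy, x$fld$training_accuracy))
  invisible(x)
}

format_csv_num <- function(df) {
  for (col in names(df)) {
    if (is.numeric(df[[col]]) && !is.integer(df[[col]])) {
      df[[col]] <- trimws(formatC(df[[col]], digits = 12, format = "g"))
    }
  }
  df
}

#' Write a pipeline report to disk
#'
#' Emits `fits.csv`, `fld_model.json`, `projections.csv`,
#' `probabilities.csv`, `baselines.csv` and `run.json` (configuration,
#' split, classification summary, logistic model, Kullback test, timings,
#' package version) with stable column ordering. Floats in the CSVs are
#' fixed to 12 significant digits so identical runs are byte-identical.
#'
#' @param report a `run_report`.
#' @param output_dir output directory, created if missing.
#' @return `output_dir`, invisibly.
#' @export
write_report <- function(report, output_dir) {
  if (!dir.exists(output_dir)) {
    ok <- dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(output_dir)) {
      stop("cannot create output directory: ", output_dir, call. = FALSE)
    }
  }
  wcsv <- function(df, name) {
    utils::write.csv(format_csv_num(df), file.path(output_dir, name),
                     row.names = FALSE, quote = FALSE)
  }
  wcsv(report$fits, "fits.csv")
  wcsv(report$projections, "projections.csv")
  wcsv(report$probabilities, "probabilities.csv")
  wcsv(report$baselines, "baselines.csv")
  fld_save_json(report$fld, file.path(output_dir, "fld_model.json"))
  cfg <- report$config
  run_meta <- list(
    config = list(
      label_a = cfg$label_a, label_b = cfg$label_b,
      train_count = cfg$train_count, seed = cfg$seed,
      alpha_t = cfg$alpha_t, alpha_chi = cfg$alpha_chi,
      max_lag = cfg$max_lag, r_squared = cfg$r_squared,
      decision_rule = cfg$decision_rule, lr_on = cfg$lr_on,
      spreading_threshold = cfg$spreading_threshold
    ),
    split = report$split,
    classification = list(
      accuracy = report$classification$accuracy,
      per_class_hits = as.list(report$classification$per_class_hits),
      confusion = as.data.frame(report$classification$confusion)
    ),
    training_accuracy = report$fld$training_accuracy,
    logistic = unclass(report$lr),
    kullback = report$kullback,
    timings = report$timings,
    package_version = as.character(utils::packageVersion("scampi"))
  )
  jsonlite::write_json(run_meta, file.path(output_dir, "run.json"),
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  invisible(output_dir)
}
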