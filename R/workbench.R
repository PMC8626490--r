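# Dataset containers and experiment orchestration.
#
# A dataset container is a directory: `meta.json` (format version, imaging
# profile, seed), `index.json` (cine -> split), and one serialized cine per
# file. Containers are runtime artifacts; arrays are stored in R's native
# serialization.

CONTAINER_VERSION <- 1L

#' Create an empty dataset container
#'
#' @param path directory to create.
#' @param prof the [simulator_profile()] the cines will use.
#' @param seed the seed that will drive generation (recorded in metadata).
#' @param overwrite allow reuse of an existing container directory.
#' @return container handle (list with `path` and `meta`).
#' @export
create_container <- function(path, prof, seed = NA, overwrite = FALSE) {
  if (file.exists(file.path(path, "meta.json")) && !overwrite)
    stopf("container exists at '%s'; pass overwrite = TRUE to replace", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  meta <- list(format_version = CONTAINER_VERSION,
               profile = prof$profile, matrix_size = prof$matrix_size,
               pixel_spacing = prof$pixel_spacing,
               tag_spacing = prof$tag_spacing,
               pools = prof$pools, seed = seed)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(), file.path(path, "index.json"))
  list(path = path, meta = meta)
}

#' Open an existing dataset container
#'
#' @param path container directory.
#' @return container handle.
#' @export
open_container <- function(path) {
  mf <- file.path(path, "meta.json")
  if (!file.exists(mf)) stopf("no container at '%s'", path)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      meta$format_version != CONTAINER_VERSION)
    stopf("container format version %s not supported (expected %d): %s",
          meta$format_version %||% "<none>", CONTAINER_VERSION,
          "regenerate the dataset with this package version")
  list(path = path, meta = meta)
}

#' @rdname open_container
#' @param con container handle.
#' @return `container_index()`: tibble with `cine`, `split`, `file`.
#' @export
container_index <- function(con) {
  idx <- jsonlite::read_json(file.path(con$path, "index.json"),
                             simplifyVector = TRUE)
  if (length(idx) == 0)
    return(tibble::tibble(cine = integer(), split = character(),
                          file = character()))
  tibble::as_tibble(idx)
}

#' Write one cine into a container
#'
#' @param con container handle.
#' @param k cine number.
#' @param cine a `simulated_cine` (truth may be absent for prediction-only
#'   containers).
#' @param split split label (`"train"`, `"val"`, `"test"`).
#' @param shuffled optional list (per frame) of tile-shuffled channel sets
#'   stored alongside the originals for the training split.
#' @export
write_cine <- function(con, k, cine, split = "test", shuffled = NULL) {
  file <- sprintf("cine_%04d.rds", k)
  saveRDS(list(frames = cine$frames, truth = cine$truth,
               displacement = cine$displacement, geom = cine$geom,
               motion = cine$motion, acq = cine$acq, prof = cine$prof,
               shuffled = shuffled, split = split),
          file.path(con$path, file))
  idx <- container_index(con)
  idx <- dplyr::bind_rows(idx[idx$cine != k, ],
                          tibble::tibble(cine = k, split = split,
                                         file = file))
  jsonlite::write_json(idx[order(idx$cine), ],
                       file.path(con$path, "index.json"))
  invisible(con)
}

#' @rdname write_cine
#' @return `read_cine()`: the stored `simulated_cine` (with `truth = NULL`
#'   when the container holds predictions only).
#' @export
read_cine <- function(con, k) {
  obj <- readRDS(file.path(con$path, sprintf("cine_%04d.rds", k)))
  obj$truth <- if (is.null(obj$truth)) NULL else
    lapply(obj$truth, function(x) { class(x) <- "principal_strain"; x })
  obj$frames <- lapply(obj$frames, function(x) {
    class(x) <- "tagged_pair"; x })
  class(obj) <- "simulated_cine"
  obj
}

#' Export a strain map (or image) as PNG
#'
#' Strain maps use a fixed blue-white-red diverging colormap over
#' \[-0.5, 0.5\]; plain images are rendered in grayscale over their range.
#'
#' @param x a matrix or `principal_strain` (both channels exported).
#' @param path output file (for a `principal_strain`, `_p1`/`_p2` suffixes
#'   are inserted).
#' @param range color scale limits.
#' @export
export_png <- function(x, path, range = c(-0.5, 0.5)) {
  if (!requireNamespace("png", quietly = TRUE))
    stopf("the 'png' package is required for PNG export")
  write_one <- function(m, p, rg) {
    v <- (pmin(pmax(m, rg[1]), rg[2]) - rg[1]) / diff(rg)
    if (identical(rg, c(-0.5, 0.5))) {
      r <- ifelse(v >= 0.5, 1, 2 * v)
      b <- ifelse(v <= 0.5, 1, 2 * (1 - v))
      g <- 1 - 2 * abs(v - 0.5)
      img <- array(c(r, g, b), c(nrow(m), ncol(m), 3))
    } else img <- array(rep(v, 3), c(nrow(m), ncol(m), 3))
    png::writePNG(img, p)
  }
  if (inherits(x, "principal_strain")) {
    base <- sub("\\.png$", "", path)
    write_one(x$eps_p1, paste0(base, "_p1.png"), range)
    write_one(x$eps_p2, paste0(base, "_p2.png"), range)
  } else {
    write_one(x, path, range(x))
  }
  invisible(path)
}

#' Experiment configuration
#'
#' A declarative description of a full run: simulate a dataset, analyze it
#' with HARP and/or a trained network, evaluate against ground truth. The
#' configuration round-trips losslessly through JSON and its hash stamps
#' every artifact the run produces.
#'
#' @param mode `"harp"`, `"train"`, or `"both"`.
#' @param profile simulator profile name (`"full"` or `"desk"`).
#' @param split named cine counts (default the full-scale design
#'   `c(train = 300, val = 100, test = 200)`; use a small test-only split
#'   for HARP runs).
#' @param n_frames,peak_frame cine layout.
#' @param fwhm_set HARP filter widths to sweep.
#' @param scheme training scheme name.
#' @param epochs,width_scale training settings.
#' @param seed master seed.
#' @param out_dir output directory for containers and reports.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(mode = c("harp", "train", "both"),
                              profile = "full",
                              split = c(train = 300, val = 100, test = 200),
                              n_frames = 7, peak_frame = 4,
                              fwhm_set = c(8, 12, 16, 20, 24, 28),
                              scheme = "g-only", epochs = 30,
                              width_scale = 1 / 8, seed = 1,
                              out_dir = tempfile("tagstrain_run_")) {
  structure(list(mode = match.arg(mode), profile = profile,
                 split = as.list(split), n_frames = n_frames,
                 peak_frame = peak_frame, fwhm_set = fwhm_set,
                 scheme = scheme, epochs = epochs,
                 width_scale = width_scale, seed = seed, out_dir = out_dir),
            class = "experiment_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config)[sort(names(unclass(config)))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Assemble network training samples (x = normalized tag pair, y = truth)
# from the train/val splits of a container, including tile-shuffled copies.
container_samples <- function(con, split = "train") {
  idx <- container_index(con)
  idx <- idx[idx$split == split, ]
  out <- list()
  for (k in idx$cine) {
    cine <- read_cine(con, k)
    n <- nrow(cine$frames[[1]]$I_h)
    for (i in seq_along(cine$frames)) {
      fr <- normalize_pair(cine$frames[[i]])
      tr <- cine$truth[[i]]
      out[[length(out) + 1]] <- list(
        x = array(c(fr$I_h, fr$I_v), c(n, n, 2)),
        y = array(c(tr$eps_p1, tr$eps_p2), c(n, n, 2)))
      if (!is.null(cine$shuffled)) {
        sh <- cine$shuffled[[i]]
        sc <- max(abs(sh$I_h), abs(sh$I_v), 1e-12)
        out[[length(out) + 1]] <- list(
          x = array(c(sh$I_h / sc, sh$I_v / sc), c(n, n, 2)),
          y = array(c(sh$eps_p1, sh$eps_p2), c(n, n, 2)))
      }
    }
  }
  out
}

# Stream a container's test split through HARP at several filter widths,
# pooling moving-tissue pixels; returns per-FWHM comparisons.
harp_evaluate_container <- function(con, fwhm_set = c(8, 12, 16, 20, 24, 28),
                                    mask = c("organs", "all")) {
  mask <- match.arg(mask)
  idx <- container_index(con)
  idx <- idx[idx$split == "test", ]
  acc <- list()
  for (f in as.character(fwhm_set))
    acc[[f]] <- list(e1 = list(), r1 = list(), e2 = list(), r2 = list())
  for (k in idx$cine) {
    cine <- read_cine(con, k)
    for (i in seq_along(cine$frames)) {
      fr <- cine$frames[[i]]; tr <- cine$truth[[i]]
      m <- if (mask == "organs") fr$masks$lv | fr$masks$liver
           else matrix(TRUE, nrow(fr$I_h), ncol(fr$I_h))
      for (f in as.character(fwhm_set)) {
        est <- harp_strain(fr, as.numeric(f))
        sel <- m & est$mask
        acc[[f]]$e1[[length(acc[[f]]$e1) + 1]] <- est$eps_p1[sel]
        acc[[f]]$r1[[length(acc[[f]]$r1) + 1]] <- tr$eps_p1[sel]
        acc[[f]]$e2[[length(acc[[f]]$e2) + 1]] <- est$eps_p2[sel]
        acc[[f]]$r2[[length(acc[[f]]$r2) + 1]] <- tr$eps_p2[sel]
      }
    }
  }
  purrr::map_dfr(as.character(fwhm_set), function(f) {
    a <- acc[[f]]
    tibble::tibble(
      fwhm = as.numeric(f),
      channel = c("eps_p1", "eps_p2"),
      R = c(stats::cor(unlist(a$e1), unlist(a$r1)),
            stats::cor(unlist(a$e2), unlist(a$r2))),
      mean_abs_err = c(mean(abs(unlist(a$e1) - unlist(a$r1))),
                       mean(abs(unlist(a$e2) - unlist(a$r2)))),
      n_pixels = length(unlist(a$e1)))
  })
}

#' Run a configured experiment end to end
#'
#' Simulates the dataset container, runs the configured analyses (a HARP
#' filter-width sweep and/or network training), evaluates against ground
#' truth, and writes a report bundle: `report.csv` (per-method pooled
#' correlations), `loss_curves.csv` for training runs, and
#' `manifest.json` (package version, config, config hash, artifact
#' hashes). Every stage is seeded from `config$seed`.
#'
#' @param config an [experiment_config()].
#' @param verbose print stage progress.
#' @return list with `report` (tibble), `model` (if trained), `losses`,
#'   `manifest`, `paths`.
#' @export
run_experiment <- function(config = experiment_config(), verbose = FALSE) {
  t0 <- Sys.time()
  prof <- simulator_profile(config$profile)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(config$out_dir, "dataset")
  say <- function(...) if (verbose) message(sprintf(...))
  say("stage simulate: %d cines (%s profile)",
      sum(unlist(config$split)), config$profile)
  split <- unlist(config$split)
  con <- generate_dataset(data_dir, n_cines = sum(split), split = split,
                          prof = prof, n_frames = config$n_frames,
                          peak_frame = config$peak_frame,
                          seed = config$seed, overwrite = TRUE)
  report <- NULL; model <- NULL; losses <- NULL
  if (config$mode %in% c("harp", "both")) {
    say("stage harp: FWHM sweep %s", paste(config$fwhm_set, collapse = ","))
    report <- dplyr::mutate(
      harp_evaluate_container(con, config$fwhm_set),
      method = paste0("harp_", .data$fwhm), .before = 1)
  }
  if (config$mode %in% c("train", "both")) {
    say("stage train: %s scheme, %d epochs", config$scheme, config$epochs)
    train_s <- container_samples(con, "train")
    val_s <- container_samples(con, "val")
    model <- train_strain_mapper(
      train_s, training_scheme(config$scheme), epochs = config$epochs,
      val_data = if (length(val_s)) val_s else NULL,
      width_scale = config$width_scale, seed = config$seed)
    losses <- model$losses
    utils::write.csv(losses, file.path(config$out_dir, "loss_curves.csv"),
                     row.names = FALSE)
    say("stage evaluate: network on test split")
    idx <- container_index(con)
    est <- list(); ref <- list(); msk <- list()
    for (k in idx$cine[idx$split == "test"]) {
      cine <- read_cine(con, k)
      for (i in seq_along(cine$frames)) {
        est[[length(est) + 1]] <- predict_strain(model, cine$frames[[i]])
        ref[[length(ref) + 1]] <- cine$truth[[i]]
        msk[[length(msk) + 1]] <-
          cine$frames[[i]]$masks$lv | cine$frames[[i]]$masks$liver
      }
    }
    cmp <- pixel_correlation(est, ref, msk)
    report <- dplyr::bind_rows(
      report,
      dplyr::mutate(tidy(cmp), fwhm = NA_real_, mean_abs_err = NA_real_,
                    method = paste0("cgan_", config$scheme), .before = 1))
  }
  utils::write.csv(report, file.path(config$out_dir, "report.csv"),
                   row.names = FALSE)
  files <- list.files(config$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("tagstrain")),
    r_version = R.version.string,
    config = unclass(config), config_hash = config_hash(config),
    artifact_md5 = as.list(tools::md5sum(files)),
    wall_time_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  list(report = report, model = model, losses = losses,
       manifest = manifest,
       paths = list(out = config$out_dir, dataset = data_dir))
}
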