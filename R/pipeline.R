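#' Load a run configuration
#'
#' Reads a YAML file with optional sections `network`, `training`, `loss`,
#' `targets`, `calling`, `matching`, `normalization`, `chunks`, `simulate`
#' plus top-level `seed` and `log_level`. Absent keys take the package
#' defaults (threshold 0.5, cutoff 3, alpha 0.6 / beta 0.4, learning rate
#' 1e-4, batch 16, epochs 200, ...); unknown keys are rejected so typos
#' cannot silently fall back to defaults. All values are validated by the
#' respective configuration constructors.
#'
#' @param path YAML file; an empty or missing body yields all defaults.
#' @return a `RunConfig`: named list of validated configuration objects.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("network", "training", "loss", "targets", "calling", "matching",
             "normalization", "chunks", "simulate", "seed", "log_level")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key '%s'", unknown[1]), call. = FALSE)
  }
  build <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    allowed <- names(formals(ctor))
    bad <- setdiff(names(args), allowed)
    if (length(bad)) {
      stop(sprintf("unknown key '%s' in section '%s'", bad[1], section),
           call. = FALSE)
    }
    do.call(ctor, args)
  }
  cfg <- list(
    network = build("network", network_config),
    training = build("training", train_config),
    loss = build("loss", loss_config),
    targets = build("targets", target_config),
    calling = build("calling", call_config),
    matching = build("matching", match_config),
    normalization = build("normalization", normalization_spec),
    chunks = build("chunks", chunk_plan),
    simulate = build("simulate", simulation_config),
    seed = raw$seed,
    log_level = raw$log_level %||% "info"
  )
  class(cfg) <- "RunConfig"
  cfg
}

#' Serialize a resolved run configuration
#' @param cfg a `RunConfig`.
#' @param path destination YAML file.
#' @return invisibly, `path`.
#' @export
dump_config <- function(cfg, path) {
  plain <- lapply(cfg, function(x) {
    if (is.object(x)) unclass(x) else x
  })
  yaml::write_yaml(plain, path)
  invisible(path)
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf(...))
}

# write a file atomically: produce into a temp path, then rename
atomic_write <- function(path, writer) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Run a pipeline command
#'
#' Dispatches a named pipeline step to the package operations. All
#' stochastic steps draw from the seed in `cfg$seed`, so re-running a
#' command with identical configuration reproduces identical outputs.
#' Output files are written atomically (temp-then-rename).
#'
#' Commands and their `paths` entries:
#' \describe{
#'   \item{simulate}{`out_img`, `out_csv`}
#'   \item{make-targets}{`spots` (CSV), `shape` (integer vector), `out`}
#'   \item{train}{`data_dir`, `val_dir` (paired `*.tif`/`*.csv`), `out`
#'     (checkpoint directory)}
#'   \item{enhance}{`model` (checkpoint), `input`, `output`, optional
#'     `mode` (`"2d"`/`"3d-blend"`) and `chunked = TRUE`}
#'   \item{call-spots}{`input` (enhanced image), `out` (CSV)}
#'   \item{evaluate}{`pred_dir`, `gt_dir` (aligned CSVs), `out` (JSON)}
#' }
#'
#' @param command one of the commands above.
#' @param cfg a `RunConfig` from [load_config()].
#' @param paths named list of input/output paths (see Details).
#' @return invisibly `0` on success; errors otherwise.
#' @export
run_pipeline <- function(command, cfg = load_config(), paths = list()) {
  command <- match.arg(command, c("simulate", "make-targets", "train",
                                  "enhance", "call-spots", "evaluate"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  need <- function(key) {
    if (is.null(paths[[key]])) {
      stop(sprintf("command '%s' requires path '%s'", command, key),
           call. = FALSE)
    }
    paths[[key]]
  }
  switch(command,
    "simulate" = {
      sim_cfg <- cfg$simulate
      if (!is.null(cfg$seed)) sim_cfg$seed <- cfg$seed
      sim <- simulate_field(sim_cfg)
      out_img <- need("out_img")
      write_image(sim$image, out_img)
      atomic_write(need("out_csv"), function(p) write_spot_table(sim$spots, p))
      log_msg(cfg, "simulated %d spots into %s", nrow(sim$spots), out_img)
    },
    "make-targets" = {
      spots <- read_spot_table(need("spots"))
      shape <- as.integer(need("shape"))
      tgt <- make_target(spots, shape, cfg$targets)
      write_image(tgt, need("out"))
    },
    "train" = {
      tr <- read_pair_dir(need("data_dir"))
      va <- read_pair_dir(need("val_dir"))
      model <- build_enhancement_net(cfg$network, seed = cfg$seed)
      tc <- cfg$training
      tc$seed <- cfg$seed
      model <- train_model(model, tr, va, target_cfg = cfg$targets,
                           cfg = tc, loss_cfg = cfg$loss,
                           norm_spec = cfg$normalization,
                           checkpoint_dir = need("out"))
      log_msg(cfg, "best epoch %d", attr(model, "best_epoch"))
    },
    "enhance" = {
      model <- load_checkpoint(need("model"))
      input <- need("input")
      output <- need("output")
      mode <- paths[["mode"]] %||% "2d"
      mode <- sub("-", "_", mode)
      if (isTRUE(paths[["chunked"]])) {
        enhance_chunked(model, input, output, plan = cfg$chunks, mode = mode,
                        norm_spec = cfg$normalization)
      } else {
        img <- read_image(input)
        enh <- if (mode == "2d") enhance_2d(model, img, cfg$normalization)
               else enhance_3d_blend(model, img, cfg$normalization)
        write_image(enh, output)
      }
    },
    "call-spots" = {
      img <- read_image(need("input"))
      spots <- call_spots(img, cfg$calling)
      atomic_write(need("out"), function(p) write_spot_table(spots, p))
    },
    "evaluate" = {
      preds <- sorted_csvs(need("pred_dir"))
      gts <- sorted_csvs(need("gt_dir"))
      if (length(preds) != length(gts)) {
        stop(sprintf("pairing error: %d prediction files vs %d ground-truth files",
                     length(preds), length(gts)), call. = FALSE)
      }
      rep <- evaluate_dataset(lapply(preds, read_spot_table),
                              lapply(gts, read_spot_table), cfg$matching)
      atomic_write(need("out"), function(p) {
        jsonlite::write_json(rep, p, auto_unbox = TRUE, digits = NA,
                             dataframe = "columns")
      })
      log_msg(cfg, "median F1 %.4f, median distance error %.4f",
              rep$median_f1, rep$median_distance_error)
    }
  )
  invisible(0L)
}

read_pair_dir <- function(dir) {
  imgs <- sort(list.files(dir, "\\.(tif|tiff)$", full.names = TRUE))
  if (!length(imgs)) stop("no TIFF images in ", dir, call. = FALSE)
  lapply(imgs, function(f) {
    csv <- sub("\\.(tif|tiff)$", ".csv", f)
    if (!file.exists(csv)) stop("missing annotation file ", csv, call. = FALSE)
    list(image = read_image(f), spots = read_spot_table(csv))
  })
}

sorted_csvs <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  sort(list.files(dir, "\\.csv$", full.names = TRUE))
}
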