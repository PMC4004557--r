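# Configuration loading/validation and the command dispatcher behind the
# retseg command-line script.  All nine manually tuned pipeline parameters
# are first-class keys with hard validation bounds.

retseg_defaults <- function() {
  list(
    `preprocess.tophat_radius` = 30,
    `fov.sobel_threshold`      = "auto",
    `texture.levels`           = 3,
    `texture.k`                = 8,
    `texture.hminima`          = 0.02,
    `texture.hminima_radius`   = 4,
    `texture.median_size`      = 3,
    `texture.pool_sigma`       = 8,
    `texture.override`         = NULL,
    `enhance.sigma`            = 1.5,
    `enhance.beta`             = 0.5,
    `enhance.c`                = "auto",
    `entropy.L`                = 255,
    `entropy.mask_scale`       = 0.5,
    `entropy.reflex_scale`     = 1.5,
    `entropy.reflex_channel`   = "green",
    `segment.min_fine`         = 5,
    `segment.min_coarse`       = 16,
    `segment.global_threshold` = 0.1,
    `segment.class2_reflex`    = TRUE,
    `width.gap_tolerance`      = 0
  )
}

config_ranges <- function() {
  list(
    `preprocess.tophat_radius` = c(10, 60),
    `texture.levels`           = c(2, 5),
    `texture.k`                = c(1, 64),
    `texture.hminima`          = c(1e-6, 1),
    `texture.hminima_radius`   = c(0, 16),
    `texture.median_size`      = c(1, 15),
    `texture.pool_sigma`       = c(0, 32),
    `enhance.sigma`            = c(0.5, 10),
    `enhance.beta`             = c(1e-6, 10),
    `entropy.L`                = c(15, 255),
    `entropy.mask_scale`       = c(0.3, 0.8),
    `entropy.reflex_scale`     = c(0.8, 3),
    `segment.min_fine`         = c(5, 16),
    `segment.min_coarse`       = c(5, 16),
    `segment.global_threshold` = c(0.04, 0.2),
    `width.gap_tolerance`      = c(0, 10)
  )
}

flatten_config <- function(x, prefix = NULL) {
  out <- list()
  for (nm in names(x)) {
    key <- if (is.null(prefix)) nm else paste0(prefix, ".", nm)
    val <- x[[nm]]
    if (is.list(val) && !is.null(names(val)) && !grepl("override", key)) {
      out <- c(out, flatten_config(val, key))
    } else {
      out[[key]] <- val
    }
  }
  out
}

#' Load and validate the pipeline configuration
#'
#' Precedence: built-in defaults < YAML file < explicit overrides.  Keys
#' use the dotted `module.key` form (nested YAML maps are flattened).
#' Unknown keys and out-of-range values are rejected.
#'
#' @param path Path to a YAML configuration file, or `NULL`.
#' @param overrides Named list of values taking precedence over the file.
#' @return A named list of resolved parameters (class `retseg_config`)
#'   with a `provenance` attribute naming the source of each key.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- retseg_defaults()
  prov <- stats::setNames(rep("default", length(cfg)), names(cfg))
  apply_layer <- function(layer, src) {
    layer <- flatten_config(layer)
    for (nm in names(layer)) {
      if (!nm %in% names(cfg))
        validation_error(sprintf("unknown configuration key: '%s'", nm))
      cfg[[nm]] <<- layer[[nm]]
      prov[[nm]] <<- src
    }
  }
  if (!is.null(path)) {
    if (!file.exists(path)) io_error(sprintf("config file not found: '%s'", path))
    apply_layer(yaml::read_yaml(path), "file")
  }
  if (length(overrides)) apply_layer(overrides, "flag")

  ranges <- config_ranges()
  for (nm in names(ranges)) {
    v <- cfg[[nm]]
    if (identical(v, "auto")) next
    if (!is.numeric(v) || length(v) < 1 || any(v < ranges[[nm]][1]) ||
        any(v > ranges[[nm]][2]))
      validation_error(sprintf("config '%s' = %s outside allowed range [%g, %g]",
                               nm, paste(format(v), collapse = ","),
                               ranges[[nm]][1], ranges[[nm]][2]))
  }
  if (cfg[["segment.min_fine"]] > cfg[["segment.min_coarse"]])
    validation_error("segment.min_fine must not exceed segment.min_coarse")
  if (!cfg[["entropy.reflex_channel"]] %in% c("green", "luma"))
    validation_error("entropy.reflex_channel must be 'green' or 'luma'")
  structure(cfg, provenance = prov, class = c("retseg_config", "list"))
}

parse_flags <- function(args) {
  flags <- list(); pos <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[i + 1], "--")) {
        flags[[key]] <- TRUE; i <- i + 1
      } else {
        flags[[key]] <- args[i + 1]; i <- i + 2
      }
    } else { pos <- c(pos, a); i <- i + 1 }
  }
  list(flags = flags, positional = pos)
}

#' Run a retseg command
#'
#' Dispatches the subcommands `segment`, `widths`, `evaluate` and
#' `phantom` (the interface exposed by the `inst/cli/retseg.R` script).
#'
#' @param argv Character vector of command-line tokens (subcommand first).
#' @return Integer exit status: 0 success, 1 validation/usage error,
#'   2 I/O error.
#' @export
run_command <- function(argv) {
  usage <- paste(
    "usage: retseg <command> [options]",
    "  segment INPUT --class {1,2,3} [--config cfg.yaml] --out MASK.png",
    "  widths MASK.png --out WIDTHS.csv",
    "  evaluate PRED.png GOLD.png [--fov FOV.png] --out METRICS.json",
    "  phantom [--seed N] --out-dir DIR", sep = "\n")
  if (length(argv) == 0) { message(usage); return(1L) }
  cmd <- argv[1]
  pa <- parse_flags(argv[-1])
  fl <- pa$flags; pos <- pa$positional
  read_mask <- function(path) {
    img <- read_fundus2(path)
    img > 0.5
  }
  read_fundus2 <- function(path) {            # single-channel convenience
    extract_green(read_fundus(path))
  }
  run <- function() {
    switch(cmd,
      segment = {
        if (length(pos) < 1) validation_error("segment needs an input image")
        cls <- paste0("class", if (is.null(fl$class)) "3" else fl$class)
        cfg <- load_config(fl$config)
        img <- read_fundus(pos[1])
        seg <- segment_retina(img, cfg, cls)
        if (!is.null(fl$out)) write_fundus(seg$mask, fl$out)
        if (!is.null(fl$overlay)) {
          ov <- img$pixels
          ov[, , 1][seg$mask] <- 1              # burn the mask into red
          write_fundus(fundus_image(ov), fl$overlay)
        }
        0L
      },
      widths = {
        if (length(pos) < 1) validation_error("widths needs a mask image")
        recs <- profile_vessel(read_mask(pos[1]))
        if (!is.null(fl$out)) utils::write.csv(recs, fl$out, row.names = FALSE)
        0L
      },
      evaluate = {
        if (length(pos) < 2) validation_error("evaluate needs PRED and GOLD")
        pred <- read_mask(pos[1]); gold <- read_mask(pos[2])
        fov <- if (!is.null(fl$fov)) read_mask(fl$fov) else NULL
        m <- confusion(pred, gold, fov)
        if (!is.null(fl$out))
          jsonlite::write_json(unclass(m), fl$out, auto_unbox = TRUE, digits = NA)
        if (!is.null(fl$overlay)) write_fundus(overlay_masks(pred, gold), fl$overlay)
        0L
      },
      phantom = {
        seed <- as.integer(if (is.null(fl$seed)) 1 else fl$seed)
        ph <- generate_phantom(phantom_spec(seed = seed))
        dir <- if (is.null(fl[["out-dir"]])) "." else fl[["out-dir"]]
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        write_fundus(ph$image, file.path(dir, "phantom.tif"))
        write_fundus(ph$truth$gold_mask, file.path(dir, "gold_mask.png"))
        write_fundus(ph$truth$partition_truth / 2, file.path(dir, "partition.png"))
        utils::write.csv(ph$truth$centreline_widths,
                         file.path(dir, "centreline_widths.csv"), row.names = FALSE)
        utils::write.csv(ph$truth$edge_points,
                         file.path(dir, "edge_points.csv"), row.names = FALSE)
        0L
      },
      { message(usage); 1L })
  }
  tryCatch(run(),
           retseg_io_error = function(e) { message("I/O error: ", conditionMessage(e)); 2L },
           retseg_validation_error = function(e) { message("error: ", conditionMessage(e)); 1L },
           error = function(e) { message("error: ", conditionMessage(e)); 1L })
}
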