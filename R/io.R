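# Data model and tracking-table I/O shared by all analysis stages.
# Units are nm throughout; z lies along the optical axis; time in seconds.

#' Mandatory columns of the wide tracking-table dialect
#' (one row per video frame, both channels side by side).
#' @keywords internal
TRACKING_COLUMNS <- c(
  "video_id", "cell_id", "strain_id", "role", "pair_id", "time_s",
  "x_nm_green", "y_nm_green", "z_nm_green", "intensity_green",
  "contrast_green",
  "x_nm_red", "y_nm_red", "z_nm_red", "intensity_red", "contrast_red"
)

#' Construct a cell video
#'
#' A `cell_video` is one cell's time series of paired spot observations: per
#' frame, the green and red spot's 3D position (nm), maximum intensity and
#' contrast, plus acquisition and lineage metadata. Missing frames are
#' allowed; all downstream statistics use the recorded time stamps, never
#' frame indices.
#'
#' @param video_id,cell_id,strain_id Identifiers.
#' @param role One of "mother", "daughter", "unpaired".
#' @param pair_id Lineage partner id, or `NA` iff role is "unpaired".
#' @param frame_interval Nominal time between Z-stacks (s).
#' @param stack_range Axial stack bounds c(z_min, z_max), nm.
#' @param frames data.frame with columns time_s, x/y/z_nm_green,
#'   intensity_green, contrast_green, x/y/z_nm_red, intensity_red,
#'   contrast_red; times strictly increasing.
#' @param mean_separation_nm Optional simulation ground truth carried for
#'   testing; `NA` for real data.
#' @return An object of class `"cell_video"`.
#' @export
cell_video <- function(video_id, cell_id, strain_id, role = "unpaired",
                       pair_id = NA_character_, frame_interval,
                       stack_range, frames,
                       mean_separation_nm = NA_real_) {
  role <- match.arg(role, c("mother", "daughter", "unpaired"))
  if (role == "unpaired" && !is.na(pair_id)) {
    stop("unpaired videos cannot carry a pair_id", call. = FALSE)
  }
  if (role != "unpaired" && is.na(pair_id)) {
    stop("mother/daughter videos must carry a pair_id", call. = FALSE)
  }
  needed <- setdiff(TRACKING_COLUMNS,
                    c("video_id", "cell_id", "strain_id", "role", "pair_id"))
  miss <- setdiff(needed, names(frames))
  if (length(miss)) {
    stop("frames lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(frames) > 1 && any(diff(frames$time_s) <= 0)) {
    stop("frame times must be strictly increasing in video '", video_id, "'",
         call. = FALSE)
  }
  coord_cols <- grep("^[xyz]_nm_", names(frames), value = TRUE)
  if (nrow(frames) && !all(is.finite(as.matrix(frames[coord_cols])))) {
    stop("coordinates must be finite in video '", video_id, "'",
         call. = FALSE)
  }
  structure(
    list(video_id = as.character(video_id), cell_id = as.character(cell_id),
         strain_id = as.character(strain_id), role = role,
         pair_id = as.character(pair_id),
         frame_interval = frame_interval,
         stack_range = as.numeric(stack_range),
         frames = frames, mean_separation_nm = mean_separation_nm),
    class = "cell_video"
  )
}

#' @export
print.cell_video <- function(x, ...) {
  cat(sprintf("<cell_video %s> cell %s, strain %s, role %s, %d frames, dt %g s\n",
              x$video_id, x$cell_id, x$strain_id, x$role, nrow(x$frames),
              x$frame_interval))
  invisible(x)
}

as_video_list <- function(videos) {
  if (inherits(videos, "cell_video")) list(videos) else videos
}

#' Operator-array strain geometry
#'
#' Records the genomic geometry of a two-array reporter strain: the intragenic
#' spacer `a` and the two flanking operator-array lengths. Because the
#' fluorescent signal centres on the midpoint of each array, the effective
#' genomic separation between the observed spots is
#' `z = a + 0.5 x_p + 0.5 x_q`.
#'
#' @param strain_id Identifier.
#' @param a_bp Intragenic spacer length (bp).
#' @param x_p_bp,x_q_bp Operator array lengths (bp).
#' @return Object of class `"strain_spec"` with derived `z_effective_bp`.
#' @export
strain_spec <- function(strain_id, a_bp, x_p_bp, x_q_bp) {
  z <- effective_separation(a_bp, x_p_bp, x_q_bp)
  structure(list(strain_id = as.character(strain_id), a_bp = a_bp,
                 x_p_bp = x_p_bp, x_q_bp = x_q_bp, z_effective_bp = z),
            class = "strain_spec")
}

#' Read a strain-spec table (TSV/CSV: strain_id, a_bp, x_p_bp, x_q_bp)
#' @param path File path.
#' @return Named list of [strain_spec()] objects.
#' @export
read_strain_specs <- function(path) {
  df <- read_delim_auto(path)
  need <- c("strain_id", "a_bp", "x_p_bp", "x_q_bp")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("strain-spec table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  specs <- lapply(seq_len(nrow(df)), function(i) {
    strain_spec(df$strain_id[i], df$a_bp[i], df$x_p_bp[i], df$x_q_bp[i])
  })
  names(specs) <- df$strain_id
  specs
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t"
    else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE, na.strings = c("NA", ""))
}

#' Read a tracking table (wide dialect)
#'
#' One row per (video, frame) with both channels' coordinates side by side.
#' Comma or tab delimited, autodetected. Unknown extra columns are preserved
#' on each video's frame table. Optional columns `frame_interval_s`,
#' `stack_zmin_nm`, `stack_zmax_nm` carry acquisition metadata; if absent the
#' frame interval is inferred from the median time step and the stack defaults
#' to 0--5000 nm (a 5 um stack).
#'
#' @param path File path.
#' @return A list of [cell_video()] objects, frames time-sorted.
#' @export
read_tracking_table <- function(path) {
  df <- read_delim_auto(path)
  miss <- setdiff(TRACKING_COLUMNS, names(df))
  if (length(miss)) {
    stop("tracking table lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  table_to_videos(df)
}

table_to_videos <- function(df) {
  meta_cols <- c("video_id", "cell_id", "strain_id", "role", "pair_id",
                 "frame_interval_s", "stack_zmin_nm", "stack_zmax_nm",
                 "mean_separation_nm")
  lapply(split(df, df$video_id), function(vd) {
    vd <- vd[order(vd$time_s), , drop = FALSE]
    if (anyDuplicated(vd$time_s)) {
      stop("non-increasing/duplicate times in video '", vd$video_id[1], "'",
           call. = FALSE)
    }
    fi <- if ("frame_interval_s" %in% names(vd)) vd$frame_interval_s[1]
      else if (nrow(vd) > 1) stats::median(diff(vd$time_s)) else NA_real_
    sr <- if (all(c("stack_zmin_nm", "stack_zmax_nm") %in% names(vd)))
      c(vd$stack_zmin_nm[1], vd$stack_zmax_nm[1]) else c(0, 5000)
    ms <- if ("mean_separation_nm" %in% names(vd)) vd$mean_separation_nm[1]
      else NA_real_
    frames <- vd[, setdiff(names(vd), meta_cols), drop = FALSE]
    rownames(frames) <- NULL
    cell_video(video_id = vd$video_id[1], cell_id = vd$cell_id[1],
               strain_id = vd$strain_id[1], role = vd$role[1],
               pair_id = vd$pair_id[1], frame_interval = fi,
               stack_range = sr, frames = frames, mean_separation_nm = ms)
  })
}

videos_to_table <- function(videos) {
  videos <- as_video_list(videos)
  rows <- lapply(videos, function(v) {
    if (nrow(v$frames) == 0L) return(NULL)
    cbind(
      data.frame(video_id = v$video_id, cell_id = v$cell_id,
                 strain_id = v$strain_id, role = v$role, pair_id = v$pair_id,
                 stringsAsFactors = FALSE),
      v$frames,
      data.frame(frame_interval_s = v$frame_interval,
                 stack_zmin_nm = v$stack_range[1],
                 stack_zmax_nm = v$stack_range[2],
                 mean_separation_nm = v$mean_separation_nm)
    )
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    df <- as.data.frame(
      matrix(nrow = 0, ncol = length(TRACKING_COLUMNS) + 4,
             dimnames = list(NULL, c(TRACKING_COLUMNS, "frame_interval_s",
                                     "stack_zmin_nm", "stack_zmax_nm",
                                     "mean_separation_nm")))
    )
    return(df)
  }
  do.call(rbind, rows)
}

#' Write a tracking table (wide dialect)
#'
#' Inverse of [read_tracking_table()]: deterministic column order, one row per
#' frame; an empty collection yields a header-only file.
#'
#' @param videos List of [cell_video()] objects (or a single one).
#' @param path Output path; tab-delimited unless it ends in `.csv`.
#' @export
write_tracking_table <- function(videos, path) {
  df <- videos_to_table(videos)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long (one row per spot) tracking table
#'
#' Accepts the per-spot dialect typical of spot-tracking exports: columns
#' video_id, time_s, channel (green/red), x_nm, y_nm, z_nm, intensity,
#' contrast, plus optional cell_id/strain_id/role/pair_id. Channels are paired
#' by (video_id, time): each green observation is matched to the nearest red
#' observation within `frame_interval / 2`; unmatched observations are
#' dropped.
#'
#' @param path File path.
#' @param frame_interval Nominal frame interval (s) used for the pairing
#'   tolerance; if `NULL`, inferred per video from the median green time step.
#' @return A list of [cell_video()] objects.
#' @export
read_tracking_table_long <- function(path, frame_interval = NULL) {
  df <- read_delim_auto(path)
  need <- c("video_id", "time_s", "channel", "x_nm", "y_nm", "z_nm",
            "intensity", "contrast")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("long tracking table lacks mandatory column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!all(df$channel %in% c("green", "red"))) {
    stop("channel must be 'green' or 'red'", call. = FALSE)
  }
  videos <- lapply(split(df, df$video_id), function(vd) {
    g <- vd[vd$channel == "green", , drop = FALSE]
    r <- vd[vd$channel == "red", , drop = FALSE]
    g <- g[order(g$time_s), , drop = FALSE]
    r <- r[order(r$time_s), , drop = FALSE]
    if (nrow(g) == 0L || nrow(r) == 0L) return(NULL)
    fi <- if (!is.null(frame_interval)) frame_interval
      else if (nrow(g) > 1) stats::median(diff(g$time_s)) else 1
    tol <- fi / 2
    j <- vapply(g$time_s, function(t) {
      k <- which.min(abs(r$time_s - t))
      if (abs(r$time_s[k] - t) <= tol) k else NA_integer_
    }, integer(1))
    keep <- !is.na(j)
    g <- g[keep, , drop = FALSE]
    j <- j[keep]
    if (nrow(g) == 0L) return(NULL)
    meta <- function(col, default) {
      if (col %in% names(vd)) as.character(vd[[col]][1]) else default
    }
    frames <- data.frame(
      time_s = g$time_s,
      x_nm_green = g$x_nm, y_nm_green = g$y_nm, z_nm_green = g$z_nm,
      intensity_green = g$intensity, contrast_green = g$contrast,
      x_nm_red = r$x_nm[j], y_nm_red = r$y_nm[j], z_nm_red = r$z_nm[j],
      intensity_red = r$intensity[j], contrast_red = r$contrast[j]
    )
    pid <- meta("pair_id", NA_character_)
    if (!is.na(pid) && pid == "NA") pid <- NA_character_
    cell_video(video_id = vd$video_id[1],
               cell_id = meta("cell_id", vd$video_id[1]),
               strain_id = meta("strain_id", "unknown"),
               role = meta("role", "unpaired"), pair_id = pid,
               frame_interval = fi, stack_range = c(0, 5000), frames = frames)
  })
  videos[!vapply(videos, is.null, logical(1))]
}

#' Load a pipeline configuration file
#'
#' YAML with nested sections `simulate`, `qc`, `dynamics`, `inheritance`,
#' `pipeline`; unset keys are filled with package defaults and types are
#' validated.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of class `"pipeline_config"`.
#' @export
load_config <- function(path = NULL) {
  user <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(
    simulate = list(
      sigma = 150, theta = 30, frame_interval = 6, n_frames = 100,
      noise_sd = 27.9, channel_offset = c(50, -20, 80),
      centre_sigma = 200, centre_theta = 60,
      anisotropy_mode = "isotropic", inheritance_coefficient = 0,
      n_cells = 40, fraction_paired = 0.5, n_colocalising = 20
    ),
    strains = list(
      list(strain_id = "sep71kb", a_bp = 60600, x_p_bp = 10400,
           x_q_bp = 10400)
    ),
    qc = list(contrast_min_green = 12, contrast_min_red = 12,
              intensity_min_red = 25, intensity_min_green = 16,
              z_margin = 1000, enabled = TRUE),
    dynamics = list(bin_width_s = 6, plateau_t_min_s = 150,
                    n_boot = 5000, exclude_videos = character(),
                    rv_mode = "displacement"),
    inheritance = list(n_unrelated = NULL, statistic = "mean"),
    pipeline = list(seed = 1L, bin_width_nm = 63)
  )
  cfg <- modify_defaults(defaults, user)
  numeric_keys <- list(
    c("qc", "contrast_min_green"), c("qc", "contrast_min_red"),
    c("qc", "intensity_min_red"), c("qc", "intensity_min_green"),
    c("qc", "z_margin"), c("dynamics", "bin_width_s"),
    c("dynamics", "plateau_t_min_s"), c("dynamics", "n_boot"),
    c("simulate", "sigma"), c("simulate", "theta"),
    c("simulate", "frame_interval"), c("simulate", "n_frames"),
    c("simulate", "noise_sd")
  )
  for (k in numeric_keys) {
    v <- cfg[[k[1]]][[k[2]]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("config key ", k[1], ".", k[2], " must be numeric", call. = FALSE)
    }
  }
  class(cfg) <- "pipeline_config"
  cfg
}

modify_defaults <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]])) && nm != "strains") {
      defaults[[nm]] <- modify_defaults(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Write an analysis report
#'
#' JSON (default) or TSV depending on the file extension. JSON output is
#' unboxed scalars with full precision; deterministic given fixed inputs.
#'
#' @param results A named list (JSON) or data.frame (TSV).
#' @param path Output path ending in `.json` or `.tsv`.
#' @export
write_report <- function(results, path) {
  if (grepl("\\.tsv$", path)) {
    utils::write.table(as.data.frame(results), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }
  invisible(path)
}
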