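# Landmark file I/O (named JSON, named CSV, positional TPS), YAML
# parameter files and SVG scene export.
#
# JSON and CSV round-trip coordinates bit-exactly (written with 17
# significant digits); TPS is a printed-precision format (6 decimal
# places) whose positional order is the canonical `SKULL_LANDMARKS`
# order.

detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    json = "json", csv = "csv", tps = "tps",
    stop_usage(sprintf("cannot infer landmark format from extension '.%s'",
                       ext)))
}

#' Write a skull configuration to a landmark file
#'
#' @param config A `skull_config`.
#' @param path Output path.
#' @param format `"json"`, `"csv"` or `"tps"`; inferred from the file
#'   extension by default.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(config, path, format = NULL) {
  validate_skull(config, tol = Inf)
  if (is.null(format)) format <- detect_format(path)
  lm <- config$landmarks
  switch(format,
    json = {
      # numbers are emitted at 17 significant digits so that
      # read(write(config)) reproduces every coordinate bit-exactly
      recs <- sprintf('{"name":"%s","x":%.17g,"y":%.17g,"segment":"%s"}',
                      rownames(lm), lm[, 1], lm[, 2],
                      unname(config$segments))
      writeLines(paste0('{"format":"saberlever-landmarks","version":1,',
                        '"units":"mm","landmarks":[',
                        paste(recs, collapse = ","), "]}"),
                 path)
    },
    csv = {
      lines <- c("name,x_mm,y_mm,segment",
                 sprintf("%s,%.17g,%.17g,%s", rownames(lm),
                         lm[, 1], lm[, 2], unname(config$segments)))
      writeLines(lines, path)
    },
    tps = {
      ord <- lm[SKULL_LANDMARKS, , drop = FALSE]
      lines <- c(sprintf("LM=%d", nrow(ord)),
                 sprintf("%.6f %.6f", ord[, 1], ord[, 2]),
                 "ID=saberlever")
      writeLines(lines, path)
    },
    stop_usage(sprintf("unknown landmark format '%s'", format)))
  invisible(path)
}

#' Read a skull configuration from a landmark file
#'
#' Validates that all twelve required landmarks are present (TPS files
#' are positional and mapped to the canonical `SKULL_LANDMARKS` order).
#'
#' @param path Input path.
#' @param format `"json"`, `"csv"` or `"tps"`; inferred from the file
#'   extension by default.
#' @return A `skull_config`.
#' @export
read_landmarks <- function(path, format = NULL) {
  if (!file.exists(path))
    stop_domain(sprintf("file not found: %s", path))
  if (is.null(format)) format <- detect_format(path)
  cfg <- switch(format,
    json = {
      obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e)
                        stop_domain(sprintf("JSON parse error in %s: %s",
                                            path, conditionMessage(e))))
      df <- obj$landmarks
      if (is.null(df) || !all(c("name", "x", "y") %in% names(df)))
        stop_validation(sprintf("%s: not a landmark file (no landmarks table)",
                                path))
      lm <- cbind(x = as.numeric(df$x), y = as.numeric(df$y))
      rownames(lm) <- df$name
      seg <- if (!is.null(df$segment)) {
        s <- df$segment; names(s) <- df$name; s
      } else SKULL_SEGMENTS
      new_skull_config(lm, seg)
    },
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      if (!all(c("name", "x_mm", "y_mm") %in% names(df)))
        stop_validation(sprintf("%s: expected columns name,x_mm,y_mm[,segment]",
                                path))
      lm <- cbind(x = as.numeric(df$x_mm), y = as.numeric(df$y_mm))
      rownames(lm) <- df$name
      seg <- if ("segment" %in% names(df)) {
        s <- df$segment; names(s) <- df$name; s
      } else SKULL_SEGMENTS
      new_skull_config(lm, seg)
    },
    tps = {
      lines <- trimws(readLines(path, warn = FALSE))
      lines <- lines[nzchar(lines)]
      hdr <- grep("^LM=", lines, value = TRUE)
      if (length(hdr) != 1L)
        stop_validation(sprintf("%s: TPS file needs exactly one LM= header",
                                path))
      n <- as.integer(sub("^LM=", "", hdr))
      coord_lines <- lines[(which(lines == hdr) + 1L):length(lines)]
      coord_lines <- coord_lines[!grepl("^(ID|IMAGE|SCALE)=",
                                        coord_lines)]
      if (length(coord_lines) != n)
        stop_validation(sprintf("%s: LM=%d but found %d coordinate lines",
                                path, n, length(coord_lines)))
      if (n != length(SKULL_LANDMARKS))
        stop_validation(sprintf("%s: expected %d landmarks, got %d", path,
                                length(SKULL_LANDMARKS), n))
      xy <- do.call(rbind, lapply(seq_along(coord_lines), function(i) {
        v <- suppressWarnings(as.numeric(strsplit(coord_lines[i],
                                                  "\\s+")[[1L]]))
        if (length(v) != 2L || any(!is.finite(v)))
          stop_validation(sprintf("%s: bad coordinate line %d", path, i))
        v
      }))
      rownames(xy) <- SKULL_LANDMARKS
      colnames(xy) <- c("x", "y")
      new_skull_config(xy, SKULL_SEGMENTS)
    },
    stop_usage(sprintf("unknown landmark format '%s'", format)))
  validate_skull(cfg, tol = Inf)
  cfg
}

#' Read skull parameters from a YAML file
#'
#' The YAML keys mirror the arguments of [skull_params()]; unknown keys
#' are an error.
#'
#' @param path YAML file path.
#' @return A `skull_params` object.
#' @export
read_params_yaml <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("file not found: %s", path))
  vals <- yaml::read_yaml(path)
  known <- names(formals(skull_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop_validation(paste0("unknown parameter keys: ",
                           paste(unknown, collapse = ", ")))
  do.call(skull_params, vals)
}

# ---- SVG export -------------------------------------------------------

svg_num <- function(x) sprintf("%.3f", x)

# polyline/marker elements for one configuration; colors per layer
svg_config_elems <- function(config, stroke = "#1f3552", marker_fill = stroke,
                             opacity = 1) {
  lm <- config$landmarks
  seg_path <- function(names)
    sprintf('<polyline points="%s" fill="none" stroke="%s" stroke-width="2" opacity="%s"/>',
            paste(sprintf("%s,%s", svg_num(lm[names, 1]),
                          svg_num(-lm[names, 2])), collapse = " "),
            stroke, opacity)
  elems <- c(
    seg_path(c("CAUDAL_NECK", "MID_NECK", "AOJ", "TMJ")),
    seg_path(c("TMJ", "UPPER_INCISOR_TIP")),
    seg_path(c("UPPER_CANINE_BASE", "UPPER_CANINE_TIP")),
    seg_path(c("TMJ", "LOWER_INCISOR_TIP")),
    sprintf('<circle class="landmark" id="%s" cx="%s" cy="%s" r="3" fill="%s" opacity="%s"/>',
            rownames(lm), svg_num(lm[, 1]), svg_num(-lm[, 2]),
            marker_fill, opacity))
  elems
}

svg_document <- function(body, bounds, pad = 40) {
  vb <- sprintf("%s %s %s %s",
                svg_num(bounds[1] - pad), svg_num(-bounds[4] - pad),
                svg_num(bounds[2] - bounds[1] + 2 * pad),
                svg_num(bounds[4] - bounds[3] + 2 * pad))
  c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" viewBox="%s">', vb),
    body, "</svg>")
}

config_bounds <- function(configs) {
  xy <- do.call(rbind, lapply(configs, function(c_) c_$landmarks))
  c(min(xy[, 1]), max(xy[, 1]), min(xy[, 2]), max(xy[, 2]))
}

#' Export configurations or a strike trajectory as SVG
#'
#' Mirrors the superimposed-image methodology of the rotation
#' experiments: the original configuration is drawn in one layer, a
#' transformed one (or successive strike frames) in others, with the
#' pivot and jaw-joint markers highlighted.
#'
#' @param x A `skull_config`, an `experiment_result`, a list of
#'   `experiment_result`s (one panel each) or a `strike_trajectory`.
#' @param path Output SVG path.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
export_svg <- function(x, path, ...) UseMethod("export_svg")

#' @export
export_svg.skull_config <- function(x, path, ...) {
  body <- c('<g id="original">', svg_config_elems(x), "</g>")
  writeLines(svg_document(body, config_bounds(list(x))), path)
  invisible(path)
}

#' @export
export_svg.experiment_result <- function(x, path, ...) {
  orig <- x$trial
  pivot <- x$transformed$landmarks[orig$pivot, , drop = FALSE]
  # reconstruct the original from the result is not possible in general;
  # draw the transformed configuration with the pivot and TMJ marked
  body <- c(
    '<g id="rotated">',
    svg_config_elems(x$transformed, stroke = "#a03030",
                     marker_fill = "#a03030"),
    "</g>",
    sprintf('<circle id="pivot" cx="%s" cy="%s" r="6" fill="none" stroke="#2060c0" stroke-width="2"/>',
            svg_num(pivot[1, 1]), svg_num(-pivot[1, 2])),
    sprintf('<circle id="tmj-marker" cx="%s" cy="%s" r="4" fill="#d02020"/>',
            svg_num(x$transformed$landmarks["TMJ", 1]),
            svg_num(-x$transformed$landmarks["TMJ", 2])))
  writeLines(svg_document(body, config_bounds(list(x$transformed))), path)
  invisible(path)
}

#' @export
export_svg.list <- function(x, path, original = NULL, ...) {
  if (!length(x) || !all(vapply(x, inherits, logical(1L),
                                "experiment_result")))
    stop_domain("expected a non-empty list of experiment_result objects")
  bounds <- config_bounds(lapply(x, function(r) r$transformed))
  w <- bounds[2] - bounds[1] + 80
  body <- unlist(lapply(seq_along(x), function(i) {
    r <- x[[i]]
    pv <- r$transformed$landmarks[r$trial$pivot, ]
    layers <- c(
      sprintf('<g id="panel-%s" class="panel" transform="translate(%s,0)">',
              r$trial$pivot, svg_num((i - 1) * w)),
      if (!is.null(original))
        c('<g class="original">',
          svg_config_elems(original, stroke = "#8a8a8a", opacity = 0.6),
          "</g>"),
      '<g class="rotated">',
      svg_config_elems(r$transformed, stroke = "#a03030",
                       marker_fill = "#a03030"),
      "</g>",
      sprintf('<circle class="pivot" cx="%s" cy="%s" r="6" fill="none" stroke="#2060c0" stroke-width="2"/>',
              svg_num(pv[1]), svg_num(-pv[2])),
      sprintf('<circle class="tmj-marker" cx="%s" cy="%s" r="4" fill="#d02020"/>',
              svg_num(r$transformed$landmarks["TMJ", 1]),
              svg_num(-r$transformed$landmarks["TMJ", 2])),
      "</g>")
    layers
  }))
  all_b <- bounds
  if (!is.null(original)) {
    ob <- config_bounds(list(original))
    all_b <- c(min(bounds[1], ob[1]), max(bounds[2], ob[2]),
               min(bounds[3], ob[3]), max(bounds[4], ob[4]))
  }
  all_b[2] <- all_b[2] + (length(x) - 1) * w
  writeLines(svg_document(body, all_b), path)
  invisible(path)
}

#' @export
export_svg.strike_trajectory <- function(x, path, frames = 5, ...) {
  if (!length(x$states)) stop_domain("empty trajectory")
  idx <- unique(round(seq(1, length(x$states), length.out = frames)))
  body <- unlist(lapply(seq_along(idx), function(k) {
    s <- x$states[[idx[k]]]
    alpha <- 0.3 + 0.7 * (k - 1) / max(1, length(idx) - 1)
    c(sprintf('<g id="frame-%d" class="frame">', idx[k]),
      svg_config_elems(s, stroke = "#1f3552", opacity = alpha),
      "</g>")
  }))
  trace <- sprintf('<polyline id="tip-trace" points="%s" fill="none" stroke="#c07820" stroke-width="1.5" stroke-dasharray="4 3"/>',
                   paste(sprintf("%s,%s", svg_num(x$tip_trace[, 1]),
                                 svg_num(-x$tip_trace[, 2])),
                         collapse = " "))
  vp <- sprintf('<circle id="virtual-point" cx="%s" cy="%s" r="5" fill="none" stroke="#208040" stroke-width="2"/>',
                svg_num(x$virtual_point[1]), svg_num(-x$virtual_point[2]))
  writeLines(svg_document(c(body, trace, vp),
                          config_bounds(x$states[idx])), path)
  invisible(path)
}
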