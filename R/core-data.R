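#' Construct a stroke
#'
#' A stroke is an ordered polyline drawn with a round pen. Coordinates are
#' 0-based canvas pixels, origin at the top-left, x rightward, y downward.
#'
#' @param points Numeric matrix with one `(x, y)` row per point; at least two
#'   points.
#' @param width Pen width in pixels (> 0).
#' @param index 0-based production order of the stroke within its drawing.
#' @param part_id Optional label of the object part the stroke depicts (used
#'   by the synthetic generator and the diagnosticity analyses).
#' @return A list of class `sketch_stroke`.
#' @export
stroke <- function(points, width = 5, index = 0L, part_id = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 2) {
    abort("a stroke needs a two-column (x, y) matrix with >= 2 points")
  }
  if (!is.numeric(width) || width <= 0) abort("stroke width must be > 0")
  structure(
    list(points = unname(points), width = as.numeric(width),
         index = as.integer(index), part_id = part_id),
    class = "sketch_stroke"
  )
}

validate_strokes <- function(strokes, canvas) {
  for (i in seq_along(strokes)) {
    s <- strokes[[i]]
    p <- s$points
    if (any(p[, 1] < 0) || any(p[, 1] > canvas[1]) ||
        any(p[, 2] < 0) || any(p[, 2] > canvas[2])) {
      abort(sprintf("stroke %d has points outside the %dx%d canvas",
                    s$index %||% (i - 1L), canvas[1], canvas[2]))
    }
  }
  invisible(strokes)
}

#' Rasterize strokes onto a binary canvas
#'
#' A pixel is inked iff its center lies within `pen_width / 2` (Euclidean
#' distance) of any stroke polyline segment. The result is the union over
#' strokes, so it is independent of stroke order. Pixel `(row r, col c)` of
#' the returned matrix has its center at continuous coordinates
#' `(c - 0.5, r - 0.5)`.
#'
#' @param strokes List of [stroke()] objects (possibly empty).
#' @param canvas Integer `(width, height)` of the canvas in pixels.
#' @param pen_width Default pen width in pixels for strokes that do not carry
#'   their own.
#' @return A logical `height x width` matrix.
#' @export
rasterize <- function(strokes, canvas = c(300L, 300L), pen_width = 5) {
  stopifnot(length(canvas) == 2, all(canvas >= 1))
  w <- as.integer(canvas[1]); h <- as.integer(canvas[2])
  out <- matrix(FALSE, nrow = h, ncol = w)
  if (length(strokes) == 0) return(out)
  validate_strokes(strokes, c(w, h))
  for (s in strokes) {
    rad <- (s$width %||% pen_width) / 2
    pts <- s$points
    for (seg in seq_len(nrow(pts) - 1L)) {
      p1 <- pts[seg, ]; p2 <- pts[seg + 1L, ]
      cols <- max(1L, floor(min(p1[1], p2[1]) - rad)):min(w, ceiling(max(p1[1], p2[1]) + rad) + 1L)
      rows <- max(1L, floor(min(p1[2], p2[2]) - rad)):min(h, ceiling(max(p1[2], p2[2]) + rad) + 1L)
      cx <- cols - 0.5; cy <- rows - 0.5
      dxy <- p2 - p1
      len2 <- sum(dxy^2)
      X <- matrix(cx, nrow = length(rows), ncol = length(cols), byrow = TRUE)
      Y <- matrix(cy, nrow = length(rows), ncol = length(cols))
      if (len2 == 0) {
        tt <- 0
      } else {
        tt <- ((X - p1[1]) * dxy[1] + (Y - p1[2]) * dxy[2]) / len2
        tt <- pmin(pmax(tt, 0), 1)
      }
      d2 <- (X - (p1[1] + tt * dxy[1]))^2 + (Y - (p1[2] + tt * dxy[2]))^2
      out[rows, cols] <- out[rows, cols] | (d2 <= rad^2)
    }
  }
  out
}

#' Fraction of the canvas covered in ink
#'
#' @param raster Binary (logical or 0/1) raster.
#' @return Ink fraction in `[0, 1]`.
#' @export
ink_area <- function(raster) {
  mean(raster != 0)
}

#' Assemble an interaction record
#'
#' Bundles the trial table and drawings of one dyad's communication session.
#'
#' @param dyad_id Dyad identifier.
#' @param trials Tibble with columns `dyad_id, trial_index, phase, condition,
#'   target_id, response_id, accuracy, rt_sec, repetition, n_strokes, timeout`.
#' @param drawings Tibble with columns `drawing_id, dyad_id, object_id,
#'   repetition` (appearance index 1-8), `phase, condition, strokes`
#'   (list-column of stroke lists) and optionally `features` (list-column of
#'   numeric embeddings).
#' @param roles Named character vector with `sketcher` and `viewer` ids.
#' @param validate Run [validate_interaction()]?
#' @return An object of class `interaction_record`.
#' @export
interaction_record <- function(dyad_id, trials, drawings,
                               roles = c(sketcher = paste0(dyad_id, "_s"),
                                         viewer = paste0(dyad_id, "_v")),
                               validate = TRUE) {
  rec <- structure(
    list(dyad_id = dyad_id, roles = roles,
         trials = as_tibble(trials), drawings = as_tibble(drawings)),
    class = "interaction_record"
  )
  if (validate) validate_interaction(rec)
  rec
}

#' @export
print.interaction_record <- function(x, ...) {
  cat(sprintf("<interaction_record %s: %d trials, %d drawings>\n",
              x$dyad_id, nrow(x$trials), nrow(x$drawings)))
  invisible(x)
}

#' Validate an interaction record
#'
#' Enforces the trial and drawing invariants: strictly increasing trial
#' indices, accuracy consistent with the response, response times within the
#' 30 s sketching limit unless flagged as timeouts, and each repetition block
#' targeting each repeated object exactly once.
#'
#' @param rec An [interaction_record()].
#' @return The record, invisibly; aborts with an informative message on the
#'   first violated invariant.
#' @export
validate_interaction <- function(rec) {
  tr <- rec$trials
  needed <- c("dyad_id", "trial_index", "phase", "condition", "target_id",
              "response_id", "accuracy", "rt_sec", "repetition", "n_strokes",
              "timeout")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols)) {
    abort(paste0("trial table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (any(diff(tr$trial_index) <= 0)) abort("trial_index must be strictly increasing")
  bad_acc <- which(tr$accuracy != as.integer(tr$response_id == tr$target_id))
  if (length(bad_acc)) {
    abort(sprintf("trial row %d: accuracy inconsistent with response_id vs target_id",
                  bad_acc[1]))
  }
  bad_rt <- which(tr$rt_sec > 30 & !as.logical(tr$timeout))
  if (length(bad_rt)) {
    abort(sprintf("trial row %d: rt_sec > 30 s without timeout flag", bad_rt[1]))
  }
  if (any(tr$rt_sec <= 0)) abort("rt_sec must be positive")
  rep_tr <- tr[tr$phase == "repetition", ]
  if (nrow(rep_tr)) {
    counts <- table(rep_tr$repetition, rep_tr$target_id)
    if (any(counts != 1)) {
      abort("each repetition block must target each repeated object exactly once")
    }
  }
  dw <- rec$drawings
  if (nrow(dw)) {
    ok_rep <- dw$repetition %in% 1:8
    if (!all(ok_rep)) abort("drawing repetition (appearance index) must be in 1..8")
  }
  invisible(rec)
}

trials_csv_header <- c("dyad_id", "trial_index", "phase", "condition",
                       "target_id", "response_id", "accuracy", "rt_sec",
                       "repetition", "n_strokes", "timeout")

#' Write a session to disk
#'
#' Writes the trial table as CSV (fixed column order) and the strokes as
#' JSON-lines, one object per stroke. Feature embeddings, being derived
#' quantities, are not serialized.
#'
#' @param rec An [interaction_record()] (or a list of them; their rows are
#'   concatenated).
#' @param trials_path,strokes_path Output file paths.
#' @return Invisibly, the paths.
#' @export
write_session <- function(rec, trials_path, strokes_path) {
  recs <- if (inherits(rec, "interaction_record")) list(rec) else rec
  trials <- dplyr::bind_rows(lapply(recs, `[[`, "trials"))
  trials <- trials[, trials_csv_header]
  write.csv(trials, trials_path, row.names = FALSE, na = "")
  con <- file(strokes_path, open = "wt")
  on.exit(close(con))
  for (r in recs) {
    dw <- r$drawings
    for (i in seq_len(nrow(dw))) {
      for (s in dw$strokes[[i]]) {
        obj <- list(drawing_id = dw$drawing_id[i], dyad_id = dw$dyad_id[i],
                    object_id = dw$object_id[i], repetition = dw$repetition[i],
                    phase = dw$phase[i], condition = dw$condition[i],
                    index = s$index, width = s$width,
                    points = unname(s$points))
        if (!is.na(s$part_id %||% NA)) obj$part_id <- s$part_id
        writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), con)
      }
    }
  }
  invisible(c(trials = trials_path, strokes = strokes_path))
}

#' Read a session from disk
#'
#' Inverse of [write_session()]. All invariants are validated on load;
#' strokes whose metadata match no trial are an error.
#'
#' @param trials_path Trials CSV path.
#' @param strokes_path Strokes JSON-lines path.
#' @return A list of [interaction_record()]s, one per dyad present, named by
#'   `dyad_id` (a single record is still returned in a length-1 list).
#' @export
read_session <- function(trials_path, strokes_path) {
  trials <- read.csv(trials_path, stringsAsFactors = FALSE,
                     colClasses = c(dyad_id = "character",
                                    target_id = "character",
                                    response_id = "character"))
  if (!identical(names(trials), trials_csv_header)) {
    abort(paste0("trials CSV header mismatch; expected: ",
                 paste(trials_csv_header, collapse = ",")))
  }
  trials <- as_tibble(trials)
  trials$repetition <- suppressWarnings(as.integer(trials$repetition))

  lines <- readLines(strokes_path)
  lines <- lines[nzchar(lines)]
  parsed <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e) abort(sprintf(
                      "strokes line %d: invalid JSON (%s)", i, conditionMessage(e))))
    need <- c("drawing_id", "dyad_id", "object_id", "repetition", "phase",
              "condition", "index", "width", "points")
    if (!all(need %in% names(rec))) {
      abort(sprintf("strokes line %d: missing fields", i))
    }
    parsed[[i]] <- rec
  }

  meta <- tibble(
    drawing_id = vapply(parsed, `[[`, "", "drawing_id"),
    dyad_id = vapply(parsed, `[[`, "", "dyad_id"),
    object_id = vapply(parsed, `[[`, "", "object_id"),
    repetition = vapply(parsed, function(p) as.integer(p$repetition), 0L),
    phase = vapply(parsed, `[[`, "", "phase"),
    condition = vapply(parsed, `[[`, "", "condition"),
    line = seq_along(parsed)
  )

  out <- list()
  for (dy in unique(trials$dyad_id)) {
    tr <- trials[trials$dyad_id == dy, ]
    sm <- meta[meta$dyad_id == dy, ]
    # expected appearance index per trial, used to match strokes to trials
    tr_k <- appearance_index(tr$phase, tr$repetition)
    key_tr <- paste(tr$target_id, tr$phase, tr_k)
    dw_ids <- unique(sm$drawing_id)
    rows <- vector("list", length(dw_ids))
    for (j in seq_along(dw_ids)) {
      sj <- sm[sm$drawing_id == dw_ids[j], ]
      key_dw <- paste(sj$object_id[1], sj$phase[1], sj$repetition[1])
      if (!key_dw %in% key_tr) {
        abort(sprintf("strokes line %d: drawing %s matches no trial of dyad %s",
                      sj$line[1], dw_ids[j], dy))
      }
      sl <- lapply(sj$line, function(li) {
        p <- parsed[[li]]
        pm <- p$points
        if (!is.matrix(pm)) pm <- matrix(as.numeric(unlist(pm)), ncol = 2, byrow = TRUE)
        stroke(pm, width = p$width, index = p$index,
               part_id = p$part_id %||% NA_character_)
      })
      ord <- order(vapply(sl, `[[`, 0L, "index"))
      sl <- sl[ord]
      idx <- vapply(sl, `[[`, 0L, "index")
      if (!identical(idx, seq_along(idx) - 1L)) {
        abort(sprintf("drawing %s: stroke indices not contiguous from 0", dw_ids[j]))
      }
      rows[[j]] <- tibble(
        drawing_id = dw_ids[j], dyad_id = dy, object_id = sj$object_id[1],
        repetition = sj$repetition[1], phase = sj$phase[1],
        condition = sj$condition[1], strokes = list(sl)
      )
    }
    drawings <- if (length(rows)) dplyr::bind_rows(rows) else
      tibble(drawing_id = character(), dyad_id = character(),
             object_id = character(), repetition = integer(),
             phase = character(), condition = character(), strokes = list())
    out[[dy]] <- interaction_record(dy, tr, drawings)
  }
  out
}

#' Grayscale PNG input/output
#'
#' `write_gray_png()` writes a `[0, 1]` matrix as an 8-bit grayscale PNG;
#' `read_gray_png()` reads one back to `[0, 1]`; `read_mask_png()`
#' additionally binarizes at an 8-bit threshold (default 127: values > 127/255
#' become `TRUE`).
#'
#' @param mat Numeric matrix with values in `[0, 1]`.
#' @param path File path.
#' @param threshold 8-bit binarization threshold for masks.
#' @return `read_gray_png()` a numeric matrix; `read_mask_png()` a logical
#'   matrix.
#' @export
write_gray_png <- function(mat, path) {
  stopifnot(min(mat) >= 0, max(mat) <= 1)
  png::writePNG(mat, path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' @rdname write_gray_png
#' @export
read_mask_png <- function(path, threshold = 127) {
  read_gray_png(path) > threshold / 255
}
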