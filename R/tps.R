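#' Read 2D landmark configurations from TPS text
#'
#' Parses plain TPS records (`LM=`, coordinate rows, `ID=`/`IMAGE=`,
#' `SCALE=`). If a record carries `SCALE=`, every coordinate is multiplied by
#' it so that stored coordinates are in millimetres. Curve extensions
#' (`CURVES=`/`POINTS=`) are not supported and raise an error rather than
#' being silently dropped.
#'
#' @param file Path to a TPS file, or the TPS content itself when `text` is
#'   used.
#' @param text Optional character scalar (or vector of lines) of TPS content;
#'   overrides `file`.
#' @return A landmark table (tibble: `specimen`, `point`, `x`, `y`, `side`),
#'   with `side = "unknown"` (TPS carries no side metadata).
#' @export
#' @examples
#' read_tps(text = "LM=2\n0 0\n2 0\nID=t1\nSCALE=0.5")
read_tps <- function(file = NULL, text = NULL) {
  if (is.null(text)) {
    if (is.null(file)) abort("supply `file` or `text`")
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  }
  lines <- trimws(lines)
  lines_keep <- which(lines != "")
  starts <- grep("^[Ll][Mm]=", lines)
  if (!length(starts)) abort("no TPS records found (no LM= header)")
  bad_ext <- grep("^(CURVES|POINTS)=", toupper(lines))
  if (length(bad_ext)) {
    abort(paste0("TPS curve extensions (CURVES=/POINTS=) are not supported (line ",
                 bad_ext[1], ")"))
  }
  bounds <- c(starts, length(lines) + 1L)
  out <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    block <- lines[starts[r]:(bounds[r + 1] - 1L)]
    block <- block[block != ""]
    n_lm <- suppressWarnings(as.integer(sub("^[Ll][Mm]=", "", block[1])))
    if (is.na(n_lm) || n_lm < 1) {
      abort(paste0("record ", r, ": malformed LM= header"))
    }
    keyed <- grepl("=", block, fixed = TRUE)
    coord_lines <- block[!keyed]
    if (length(coord_lines) != n_lm) {
      abort(paste0("record ", r, ": LM=", n_lm, " but found ",
                   length(coord_lines), " coordinate rows"))
    }
    coords <- matrix(NA_real_, n_lm, 2)
    for (i in seq_len(n_lm)) {
      parts <- strsplit(coord_lines[i], "[ \t]+")[[1]]
      parts <- parts[parts != ""]
      vals <- suppressWarnings(as.numeric(parts))
      if (length(vals) != 2 || anyNA(vals)) {
        line_no <- starts[r] + which(block == coord_lines[i])[1] - 1L
        abort(paste0("record ", r, ", line ", line_no,
                     ": non-numeric or non-2D coordinate row"))
      }
      coords[i, ] <- vals
    }
    keys <- block[keyed][-1]  # drop the LM= line itself
    getval <- function(key) {
      hit <- grep(paste0("^", key, "="), toupper(keys))
      if (length(hit)) sub("^[^=]*=", "", keys[hit[1]]) else NA_character_
    }
    id <- getval("ID")
    if (is.na(id)) id <- getval("IMAGE")
    if (is.na(id) || id == "") id <- paste0("specimen_", r)
    scale <- getval("SCALE")
    if (!is.na(scale)) {
      s <- suppressWarnings(as.numeric(scale))
      if (is.na(s) || s <= 0) abort(paste0("record ", r, ": invalid SCALE="))
      coords <- coords * s
    }
    out[[r]] <- tibble::tibble(specimen = id,
                               point = seq_len(n_lm),
                               x = coords[, 1], y = coords[, 2],
                               side = "unknown")
  }
  ids <- vapply(out, function(d) d$specimen[1], character(1))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate specimen ids in TPS: ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  dplyr::bind_rows(out)
}

#' Write landmark configurations to TPS text
#'
#' Coordinates are written at full double precision with `SCALE=1.0`
#' (coordinates are already in millimetres).
#'
#' @param landmarks Landmark table (see [validate_landmarks()]).
#' @param file Optional path; if `NULL` the TPS text is returned invisibly.
#' @return The TPS text, invisibly.
#' @export
write_tps <- function(landmarks, file = NULL) {
  landmarks <- validate_landmarks(landmarks)
  if (!nrow(landmarks)) abort("empty landmark table")
  sp <- unique(landmarks$specimen)
  recs <- purrr::map_chr(sp, function(s) {
    d <- dplyr::arrange(dplyr::filter(landmarks, .data$specimen == s), .data$point)
    paste0("LM=", nrow(d), "\n",
           paste(sprintf("%.17g %.17g", d$x, d$y), collapse = "\n"),
           "\nID=", s, "\nSCALE=1.0")
  })
  txt <- paste0(paste(recs, collapse = "\n"), "\n")
  if (!is.null(file)) writeLines(txt, file, sep = "")
  invisible(txt)
}

#' Mirror right-side configurations to the left side
#'
#' Reflects about the vertical axis (x -> -x, y unchanged) so that all
#' specimens are analysed as left elements; medial is -x afterwards. Only
#' `side = "right"` rows may be mirrored: mirroring a left configuration
#' errors, preventing accidental double mirroring.
#'
#' @param landmarks Landmark table with a `side` column.
#' @param specimens Specimens to mirror; default mirrors every right-side
#'   specimen.
#' @return The landmark table with mirrored coordinates and `side = "left"`
#'   for the mirrored specimens.
#' @export
mirror_landmarks <- function(landmarks, specimens = NULL) {
  landmarks <- tibble::as_tibble(landmarks)
  if (!"side" %in% names(landmarks)) abort("landmark table has no `side` column")
  if (is.null(specimens)) {
    specimens <- unique(landmarks$specimen[landmarks$side == "right"])
  }
  sel <- landmarks$specimen %in% specimens
  if (!all(landmarks$side[sel] == "right")) {
    bad <- unique(landmarks$specimen[sel & landmarks$side != "right"])
    abort(paste0("refusing to mirror non-right configurations: ",
                 paste(bad, collapse = ", ")))
  }
  landmarks$x[sel] <- -landmarks$x[sel]
  landmarks$side[sel] <- "left"
  landmarks
}

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of the points from their
#' centroid — the scale unit of generalized Procrustes analysis.
#'
#' @param config A p x 2 matrix, or a single specimen's rows of a landmark
#'   table.
#' @return Positive scalar.
#' @export
#' @examples
#' centroid_size(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)))  # sqrt(2)
centroid_size <- function(config) {
  m <- config_matrix(config)
  if (nrow(m) < 3) abort("centroid size needs at least 3 points")
  cen <- colMeans(m)
  cs <- sqrt(sum((m[, 1] - cen[1])^2 + (m[, 2] - cen[2])^2))
  if (cs <= .Machine$double.eps) abort("degenerate configuration: all points coincident")
  cs
}

#' Centroid sizes for every specimen in a landmark table
#'
#' @param landmarks Landmark table.
#' @return Tibble with `specimen` and `centroid_size`.
#' @export
centroid_sizes <- function(landmarks) {
  arr <- lm_array(landmarks)
  tibble::tibble(
    specimen = dimnames(arr)[[3]],
    centroid_size = apply(arr, 3, centroid_size)
  )
}
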