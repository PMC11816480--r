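# Praat TextGrid / PitchTier text formats.
#
# Both the verbose ("long") and the compact ("short") text dialects are
# supported.  Only interval tiers are used by the pipeline; point tiers are
# parsed and ignored.  Times are seconds throughout.

#' Read a Praat TextGrid
#'
#' Parses a TextGrid file in either the long (`item [1]: ... xmin = 0`) or
#' short (bare values) text dialect and returns every interval tier.
#'
#' @param path Path to a `.TextGrid` file.
#' @return A named list, one element per interval tier, each a tibble with
#'   columns `xmin`, `xmax` (seconds) and `label`.
#' @seealso [read_textgrid_rhymes()] for the syllable-rhyme convenience
#'   wrapper, [write_textgrid()] for the inverse.
#' @export
read_textgrid <- function(path) {
  if (!file.exists(path)) .abort(paste0("file not found: ", path), "vm_io_error")
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (length(lines) < 3 || !grepl("ooTextFile", lines[[1]]) ||
      !any(grepl("TextGrid", lines[1:2]))) {
    .abort(paste0("not a Praat TextGrid (bad header): ", path), "vm_parse_error")
  }
  body <- lines[-(1:2)]
  if (any(grepl("item\\s*\\[", body))) {
    .parse_textgrid_long(body, path)
  } else {
    .parse_textgrid_short(body, path)
  }
}

# long dialect: every value is on a "key = value" line
.parse_textgrid_long <- function(body, path) {
  num <- function(line, key, i) {
    m <- regmatches(line, regexec(paste0(key, "\\s*=\\s*(-?[0-9.eE+]+)"), line))[[1]]
    if (length(m) < 2) {
      .abort(sprintf("TextGrid parse error near line %d of %s: expected '%s = <number>'",
                     i + 2L, path, key), "vm_parse_error")
    }
    as.numeric(m[[2]])
  }
  str <- function(line) {
    m <- regmatches(line, regexec('=\\s*"(.*)"\\s*$', line))[[1]]
    if (length(m) < 2) NA_character_ else gsub('""', '"', m[[2]])
  }
  tiers <- list()
  tier_starts <- grep("item\\s*\\[[0-9]+\\]\\s*:", body)
  for (k in seq_along(tier_starts)) {
    from <- tier_starts[[k]]
    to <- if (k < length(tier_starts)) tier_starts[[k + 1]] - 1L else length(body)
    block <- body[from:to]
    cls <- str(block[grep("class\\s*=", block)[1]])
    name <- str(block[grep("name\\s*=", block)[1]])
    if (!identical(cls, "IntervalTier")) next
    idx <- grep("intervals\\s*\\[[0-9]+\\]\\s*:", block)
    ivals <- lapply(idx, function(i) {
      xmin <- num(block[i + 1L], "xmin", from + i)
      xmax <- num(block[i + 2L], "xmax", from + i + 1L)
      lab <- str(block[i + 3L])
      tibble::tibble(xmin = xmin, xmax = xmax, label = lab %||% "")
    })
    tiers[[name]] <- if (length(ivals)) dplyr::bind_rows(ivals) else
      tibble::tibble(xmin = numeric(), xmax = numeric(), label = character())
  }
  tiers
}

# short dialect: sequential bare values
.parse_textgrid_short <- function(body, path) {
  toks <- body[nzchar(trimws(body))]
  pos <- 1L
  take <- function() {
    if (pos > length(toks)) .abort(paste0("truncated short TextGrid: ", path),
                                   "vm_parse_error")
    v <- trimws(toks[[pos]])
    pos <<- pos + 1L
    v
  }
  takenum <- function() {
    v <- suppressWarnings(as.numeric(take()))
    if (is.na(v)) .abort(sprintf("TextGrid parse error near line %d of %s: expected number",
                                 pos + 1L, path), "vm_parse_error")
    v
  }
  takestr <- function() gsub('""', '"', gsub('^"|"$', "", take()))
  takenum(); takenum()                       # global xmin, xmax
  has <- take()                              # <exists> flag
  if (!grepl("exists", has)) .abort(paste0("malformed short TextGrid: ", path),
                                    "vm_parse_error")
  ntier <- takenum()
  tiers <- list()
  for (t in seq_len(ntier)) {
    cls <- takestr()
    name <- takestr()
    takenum(); takenum()                     # tier xmin, xmax
    n <- takenum()
    if (identical(cls, "IntervalTier")) {
      xmin <- xmax <- numeric(n); lab <- character(n)
      for (i in seq_len(n)) {
        xmin[[i]] <- takenum(); xmax[[i]] <- takenum(); lab[[i]] <- takestr()
      }
      tiers[[name]] <- tibble::tibble(xmin = xmin, xmax = xmax, label = lab)
    } else {
      for (i in seq_len(n)) { takenum(); takestr() }   # point tier: skip
    }
  }
  tiers
}

#' Write a TextGrid (long dialect)
#'
#' @param tiers Named list of tibbles with columns `xmin`, `xmax`, `label`,
#'   as returned by [read_textgrid()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tiers, path) {
  stopifnot(is.list(tiers), length(names(tiers)) == length(tiers))
  tmin <- min(vapply(tiers, function(t) min(t$xmin, Inf), numeric(1)), 0)
  tmax <- max(vapply(tiers, function(t) max(t$xmax, -Inf), numeric(1)), 0)
  esc <- function(s) gsub('"', '""', s)
  out <- c(
    'File type = "ooTextFile"', 'Object class = "TextGrid"', "",
    sprintf("xmin = %.10g", tmin), sprintf("xmax = %.10g", tmax),
    "tiers? <exists>", sprintf("size = %d", length(tiers)), "item []:"
  )
  for (k in seq_along(tiers)) {
    tr <- tiers[[k]]
    out <- c(out,
      sprintf("    item [%d]:", k),
      '        class = "IntervalTier"',
      sprintf('        name = "%s"', esc(names(tiers)[[k]])),
      sprintf("        xmin = %.10g", min(tr$xmin, tmin)),
      sprintf("        xmax = %.10g", max(tr$xmax, tmax)),
      sprintf("        intervals: size = %d", nrow(tr)))
    for (i in seq_len(nrow(tr))) {
      out <- c(out,
        sprintf("        intervals [%d]:", i),
        sprintf("            xmin = %.10g", tr$xmin[[i]]),
        sprintf("            xmax = %.10g", tr$xmax[[i]]),
        sprintf('            text = "%s"', esc(tr$label[[i]])))
    }
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Extract labelled syllable-rhyme intervals from a TextGrid tier
#'
#' Returns the non-empty labelled intervals of the named interval tier,
#' ordered by start time.  Empty labels mark silence / non-rhyme material
#' (standard ProsodyPro practice) and are dropped.
#'
#' @param path TextGrid file path.
#' @param tier_name Name of the interval tier holding rhyme annotations.
#' @return Tibble with columns `label`, `start_s`, `end_s`.
#' @export
read_textgrid_rhymes <- function(path, tier_name) {
  tiers <- read_textgrid(path)
  if (!tier_name %in% names(tiers)) {
    .abort(sprintf("tier '%s' not found in %s (tiers present: %s)",
                   tier_name, path, paste(names(tiers), collapse = ", ")),
           "vm_tier_absent")
  }
  tr <- tiers[[tier_name]]
  tr <- tr[!is.na(tr$label) & nzchar(trimws(tr$label)), , drop = FALSE]
  tr <- tr[order(tr$xmin), , drop = FALSE]
  tibble::tibble(label = tr$label, start_s = tr$xmin, end_s = tr$xmax)
}

#' Read a Praat PitchTier (long text dialect)
#'
#' @param path PitchTier file path.
#' @return Tibble with columns `time_s`, `f0_hz`, time-sorted.
#' @export
read_pitchtier <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!any(grepl("PitchTier", lines[1:2]))) {
    .abort(paste0("not a Praat PitchTier: ", path), "vm_parse_error")
  }
  grab <- function(key) {
    hits <- regmatches(lines, regexec(paste0(key, "\\s*=\\s*(-?[0-9.eE+]+)"), lines))
    as.numeric(vapply(Filter(function(m) length(m) == 2, hits), `[[`, "", 2))
  }
  t <- grab("number"); f <- grab("value")
  if (length(t) != length(f)) .abort(paste0("malformed PitchTier: ", path), "vm_parse_error")
  ord <- order(t)
  tibble::tibble(time_s = t[ord], f0_hz = f[ord])
}

#' Read a frame-level pitch track from CSV
#'
#' Expects header columns `time_s` and `f0_hz`; unvoiced frames may be empty
#' or 0 and are dropped.
#'
#' @param path CSV path.
#' @return Tibble with columns `time_s`, `f0_hz`, time-sorted, voiced only.
#' @export
read_pitch_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "f0_hz") %in% names(df))) {
    .abort(paste0("pitch CSV must have columns time_s,f0_hz: ", path), "vm_parse_error")
  }
  df <- df[!is.na(df$f0_hz) & df$f0_hz > 0, c("time_s", "f0_hz")]
  df <- df[order(df$time_s), ]
  tibble::as_tibble(df)
}

#' Median F0 over a syllable-rhyme window
#'
#' Computes the median of the voiced pitch samples whose times fall in the
#' half-open window `[start_s, end_s)`.  Half-open membership prevents a
#' sample sitting exactly on a rhyme boundary from being counted twice by
#' adjacent rhymes.
#'
#' @param pitch_points Tibble/data.frame with columns `time_s`, `f0_hz`,
#'   time-sorted.
#' @param start_s,end_s Window bounds in seconds, `start_s < end_s`.
#' @return Median F0 in Hz, or `NA_real_` when no voiced sample falls in the
#'   window (e.g. a fully creaky rhyme).
#' @export
median_f0_for_interval <- function(pitch_points, start_s, end_s) {
  stopifnot(is.data.frame(pitch_points),
            all(c("time_s", "f0_hz") %in% names(pitch_points)))
  if (!(start_s < end_s)) .abort("start_s must be < end_s", "vm_bad_window")
  if (is.unsorted(pitch_points$time_s, strictly = FALSE)) {
    .abort("pitch points must be time-sorted", "vm_unsorted_pitch")
  }
  inside <- pitch_points$time_s >= start_s & pitch_points$time_s < end_s &
    !is.na(pitch_points$f0_hz) & pitch_points$f0_hz > 0
  if (!any(inside)) return(NA_real_)
  median(pitch_points$f0_hz[inside])
}
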