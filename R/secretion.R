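#' Parse SignalP 5 "short" output
#'
#' Reads the eukaryote-mode short tabular output: `#`-prefixed header lines,
#' then one tab-separated line per protein with columns ID, Prediction
#' (`SP(Sec/SPI)` or `OTHER`), the two probabilities, and an optional
#' cleavage-site column of the form `CS pos: 18-19. Pr: 0.6838`.
#'
#' The probability columns are parsed but not re-thresholded; the Prediction
#' label (SignalP's own decision) is authoritative.
#'
#' @param path path to a SignalP 5 short file.
#' @return data frame with columns `protein_id`, `prediction`,
#'   `sp_probability`, `other_probability`, `cs_from`, `cs_to` (NA when no
#'   cleavage site is reported). Duplicate protein ids keep the first call
#'   with a warning.
#' @export
parse_signalp_short <- function(path) {
  if (!file.exists(path)) stop("SignalP file not found: ", path)
  lines <- readLines(path)
  lines_keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  data_lines <- lines[lines_keep]
  lineno <- which(lines_keep)
  out <- data.frame(
    protein_id = character(), prediction = character(),
    sp_probability = numeric(), other_probability = numeric(),
    cs_from = integer(), cs_to = integer(), stringsAsFactors = FALSE
  )
  if (length(data_lines) == 0L) return(out)
  fields <- strsplit(data_lines, "\t")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    i <- which(nf < 4L)[1]
    stop("SignalP line ", lineno[i], " has ", nf[i], " columns; >= 4 expected")
  }
  id <- vapply(fields, `[[`, character(1), 1)
  pred <- vapply(fields, `[[`, character(1), 2)
  parse_prob <- function(k, what) {
    x <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), k)))
    if (anyNA(x) || any(x < 0 | x > 1)) {
      i <- which(is.na(x) | x < 0 | x > 1)[1]
      stop("malformed ", what, " probability on SignalP line ", lineno[i])
    }
    x
  }
  sp <- parse_prob(3, "SP(Sec/SPI)")
  other <- parse_prob(4, "OTHER")
  cs <- vapply(fields, function(f) if (length(f) >= 5) f[[5]] else "", character(1))
  cs_from <- rep(NA_integer_, length(id))
  cs_to <- rep(NA_integer_, length(id))
  has_cs <- grepl("CS pos:", cs)
  if (any(has_cs)) {
    m <- regmatches(cs, regexec("CS pos:\\s*(\\d+)-(\\d+)", cs))
    cs_from[has_cs] <- as.integer(vapply(m[has_cs], `[[`, character(1), 2))
    cs_to[has_cs] <- as.integer(vapply(m[has_cs], `[[`, character(1), 3))
  }
  dup <- duplicated(id)
  if (any(dup)) {
    warning("duplicate SignalP protein id(s): ",
            paste(unique(id[dup]), collapse = ", "), "; keeping first")
  }
  data.frame(
    protein_id = id, prediction = pred, sp_probability = sp,
    other_probability = other, cs_from = cs_from, cs_to = cs_to,
    stringsAsFactors = FALSE
  )[!dup, , drop = FALSE]
}

#' Is a protein predicted to be secreted?
#'
#' True iff the SignalP prediction label is `SP(Sec/SPI)`. Proteins without a
#' call (join misses) are treated as not secreted.
#'
#' @param calls data frame from [parse_signalp_short()].
#' @return logical vector.
#' @export
is_secreted <- function(calls) {
  calls$prediction == "SP(Sec/SPI)"
}
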