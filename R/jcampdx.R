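#' Write a spectrum as a JCAMP-DX file
#'
#' Emits an NTUPLES record with two AFFN data-table pages (real and imaginary
#' spectrum) in the `(X++(R..R))` / `(X++(I..I))` layout. The original axis
#' orientation of the source data is restored on output (NMR convention:
#' descending ppm). All values are formatted with 17 significant digits, so a
#' write/read round trip reproduces doubles essentially exactly; the ppm axis
#' must be uniform (JCAMP tabular data assumes equidistant abscissae).
#'
#' @param spec An [nmr_spectrum()].
#' @param path Output file path.
#' @param title `##TITLE=` record content.
#' @return Invisibly, `path`.
#' @export
write_jcampdx <- function(spec, path, title = "nmrlcm spectrum") {
  stopifnot(is_nmr_spectrum(spec))
  if (length(spec$ppm) < 2L) stop("refusing to write a degenerate spectrum")
  grid_spacing(spec$ppm)  # errors on non-uniform grids
  ppm <- spec$ppm
  re <- Re(spec$intensity)
  im <- Im(spec$intensity)
  if (spec$orientation == "descending") {
    ppm <- rev(ppm); re <- rev(re); im <- rev(im)
  }
  n <- length(ppm)
  num <- function(x) sprintf("%.17g", x)
  page <- function(y, sym) {
    per_line <- 4L
    starts <- seq(1L, n, by = per_line)
    lines <- vapply(starts, function(s) {
      e <- min(s + per_line - 1L, n)
      paste(c(num(ppm[s]), num(y[s:e])), collapse = " ")
    }, character(1))
    c(sprintf("##PAGE= N=%d", if (sym == "R") 1L else 2L),
      sprintf("##DATA TABLE= (X++(%s..%s)), XYDATA", sym, sym),
      lines)
  }
  out <- c(
    sprintf("##TITLE= %s", title),
    "##JCAMP-DX= 5.01",
    "##DATA TYPE= NMR SPECTRUM",
    "##DATA CLASS= NTUPLES",
    "##ORIGIN= nmrlcm",
    "##OWNER= nmrlcm",
    sprintf("##NPOINTS= %d", n),
    "##XUNITS= PPM",
    "##NTUPLES= NMR SPECTRUM",
    "##VAR_NAME= FREQUENCY, SPECTRUM/REAL, SPECTRUM/IMAG",
    "##SYMBOL= X, R, I",
    "##VAR_TYPE= INDEPENDENT, DEPENDENT, DEPENDENT",
    "##VAR_FORM= AFFN, AFFN, AFFN",
    sprintf("##VAR_DIM= %d, %d, %d", n, n, n),
    "##UNITS= PPM, ARBITRARY UNITS, ARBITRARY UNITS",
    sprintf("##FIRST= %s, %s, %s", num(ppm[1L]), num(re[1L]), num(im[1L])),
    sprintf("##LAST= %s, %s, %s", num(ppm[n]), num(re[n]), num(im[n])),
    "##FACTOR= 1, 1, 1",
    page(re, "R"),
    page(im, "I"),
    "##END NTUPLES= NMR SPECTRUM",
    "##END="
  )
  con <- suppressWarnings(try(file(path, open = "wb"), silent = TRUE))
  if (inherits(con, "try-error")) stop("cannot write to ", path)
  on.exit(close(con))
  writeLines(out, con, sep = "\n")
  invisible(path)
}

# ---- ASDF decoding -------------------------------------------------------

# pseudo-digit tables (JCAMP-DX compressed ordinate forms)
.sqz_pos <- stats::setNames(0:9, c("@", LETTERS[1:9]))
.sqz_neg <- stats::setNames(-(1:9), letters[1:9])
.dif_pos <- stats::setNames(0:9, c("%", LETTERS[10:18]))
.dif_neg <- stats::setNames(-(1:9), letters[10:18])
.dup_tab <- stats::setNames(1:9, c(LETTERS[19:26], "s"))

# internal: decode the ordinates of one tabular data line (x token removed).
# Supports AFFN, SQZ, DIF and DUP; anything else is rejected with the name
# of the offending token. Returns list(y, ended_in_dif).
decode_asdf_line <- function(body, prev_last = NULL) {
  pat <- "[+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?|[@A-Za-z%][0-9]*"
  toks <- regmatches(body, gregexpr(pat, body))[[1]]
  leftover <- gsub("[ \t,;]+", "", gsub(pat, "", body))
  if (nchar(leftover))
    stop("JCAMP-DX: unsupported data form (unrecognised characters \"",
         leftover, "\"); only AFFN, SQZ, DIF and DUP ordinates are supported")
  y <- numeric(0)
  last_mode <- "none"   # "abs" or "dif"
  last_dif <- NA_real_
  started_with_dif <- FALSE
  for (tk in toks) {
    c1 <- substr(tk, 1L, 1L)
    rest <- substr(tk, 2L, nchar(tk))
    if (grepl("^[+-]?[0-9.]", tk)) {           # plain AFFN ordinate
      y <- c(y, as.numeric(tk))
      last_mode <- "abs"
    } else if (c1 %in% names(.sqz_pos) || c1 %in% names(.sqz_neg)) {
      d <- if (c1 %in% names(.sqz_pos)) .sqz_pos[[c1]] else .sqz_neg[[c1]]
      v <- as.numeric(paste0(d, rest))
      if (d < 0) v <- -as.numeric(paste0(-d, rest))
      y <- c(y, v)
      last_mode <- "abs"
    } else if (c1 %in% names(.dif_pos) || c1 %in% names(.dif_neg)) {
      d <- if (c1 %in% names(.dif_pos)) .dif_pos[[c1]] else .dif_neg[[c1]]
      v <- if (d < 0) -as.numeric(paste0(-d, rest)) else
        as.numeric(paste0(d, rest))
      base <- if (length(y)) y[length(y)] else prev_last
      if (is.null(base) || is.na(base))
        stop("JCAMP-DX: DIF ordinate with no preceding value")
      if (!length(y)) started_with_dif <- TRUE
      y <- c(y, base + v)
      last_dif <- v
      last_mode <- "dif"
    } else if (c1 %in% names(.dup_tab)) {
      cnt <- as.numeric(paste0(.dup_tab[[c1]], rest))
      if (last_mode == "none") stop("JCAMP-DX: DUP with no preceding token")
      # DUP repeats the previous token (cnt includes the original occurrence)
      for (r in seq_len(cnt - 1L)) {
        if (last_mode == "dif") y <- c(y, y[length(y)] + last_dif)
        else y <- c(y, y[length(y)])
      }
    } else {
      stop("JCAMP-DX: unsupported data form (token \"", tk,
           "\"); only AFFN, SQZ, DIF and DUP ordinates are supported")
    }
  }
  list(y = y, ended_in_dif = (last_mode == "dif"),
       started_with_dif = started_with_dif)
}

# internal: decode a block of tabular (X++(Y..Y)) lines into a y vector.
# Each line starts with an x token (AFFN) followed by ordinates. When a line
# follows one that ended in DIF mode, its first ordinate is a check value
# duplicating the previous line's last ordinate, and is dropped.
decode_tabular_block <- function(lines) {
  ys <- numeric(0)
  prev_dif <- FALSE
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nchar(ln)) next
    m <- regexpr("^[+-]?[0-9]*\\.?[0-9]+(?:[eE][+-]?[0-9]+)?", ln)
    if (m == -1L) stop("JCAMP-DX: data line without a leading abscissa: ", ln)
    body <- trimws(substring(ln, attr(m, "match.length") + 1L))
    dec <- decode_asdf_line(body, prev_last = if (length(ys)) ys[length(ys)])
    yl <- dec$y
    if (prev_dif && length(yl)) {
      if (length(ys) && abs(yl[1L] - ys[length(ys)]) >
          1e-6 * max(1, abs(ys[length(ys)])))
        warning("JCAMP-DX: DIF check value mismatch")
      yl <- yl[-1L]
    }
    ys <- c(ys, yl)
    prev_dif <- dec$ended_in_dif
  }
  ys
}

# internal: parse "##KEY= value" records into a named list (last wins);
# returns list(records, data_blocks) where data_blocks are the indices
parse_jcamp_records <- function(lines) {
  is_rec <- grepl("^\\s*##", lines)
  keys <- character(0); vals <- character(0); starts <- integer(0)
  for (i in which(is_rec)) {
    m <- regmatches(lines[i], regexec("^\\s*##([^=]*)=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) == 3L) {
      keys <- c(keys, toupper(gsub("[ _-]", "", m[2])))
      vals <- c(vals, trimws(m[3]))
      starts <- c(starts, i)
    }
  }
  list(keys = keys, vals = vals, starts = starts)
}

#' Read a JCAMP-DX spectrum
#'
#' Supports two layouts: an NTUPLES record with real and imaginary pages
#' (`(X++(R..R))` and `(X++(I..I))` data tables), and a pair of `##XYDATA=
#' (X++(Y..Y))` blocks in one file, the first taken as the real and the
#' second as the imaginary trace. Ordinates may be in AFFN or in the basic
#' ASDF compressed forms SQZ, DIF and DUP; other dialects are rejected with
#' an error naming the offending form. The ppm axis is constructed from
#' `##FIRST/##LAST` (NTUPLES) or `##FIRSTX/##LASTX` (with `##XFACTOR`) and
#' canonicalised to ascending order, recording the source orientation.
#'
#' @param path Path to a `.jdx`/`.dx` file.
#' @return An [nmr_spectrum()]; `meta` records source path and title.
#' @export
read_jcampdx <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- parse_jcamp_records(lines)
  getv <- function(key) {
    i <- which(rec$keys == key)
    if (length(i)) rec$vals[max(i)] else NULL
  }
  split_num <- function(v) as.numeric(strsplit(v, "[,;]\\s*")[[1]])
  title <- getv("TITLE")

  # locate tabular blocks: DATA TABLE pages (NTUPLES) or XYDATA records
  tab_idx <- which(rec$keys %in% c("DATATABLE", "XYDATA"))
  if (!length(tab_idx))
    stop("JCAMP-DX: no XYDATA or NTUPLES DATA TABLE found in ", path)
  blocks <- lapply(tab_idx, function(j) {
    from <- rec$starts[j] + 1L
    nxt <- rec$starts[rec$starts > rec$starts[j]]
    to <- if (length(nxt)) min(nxt) - 1L else length(lines)
    list(kind = rec$keys[j], form = rec$vals[j],
         lines = if (from <= to) lines[from:to] else character(0))
  })

  re <- NULL; im <- NULL
  xfirst <- NULL; xlast <- NULL
  rfac <- 1; ifac <- 1
  ntuples <- any(vapply(blocks, function(b) b$kind == "DATATABLE", logical(1)))
  if (ntuples) {
    fac <- getv("FACTOR")
    sym <- getv("SYMBOL")
    if (!is.null(fac) && !is.null(sym)) {
      syms <- trimws(strsplit(sym, ",")[[1]])
      facs <- split_num(fac)
      rfac <- facs[match("R", syms)]
      ifac <- facs[match("I", syms)]
      if (is.na(rfac)) rfac <- 1
      if (is.na(ifac)) ifac <- 1
    }
    fst <- getv("FIRST"); lst <- getv("LAST")
    if (is.null(fst) || is.null(lst))
      stop("JCAMP-DX: NTUPLES record lacks ##FIRST/##LAST; cannot build ",
           "the ppm axis")
    xfirst <- split_num(fst)[1L]
    xlast <- split_num(lst)[1L]
    for (b in blocks) {
      if (b$kind != "DATATABLE") next
      y <- decode_tabular_block(b$lines)
      if (grepl("R\\.\\.R", b$form)) re <- y * rfac
      else if (grepl("I\\.\\.I", b$form)) im <- y * ifac
      else stop("JCAMP-DX: unrecognised data table form: ", b$form)
    }
  } else {
    xf <- getv("XFACTOR"); yf <- getv("YFACTOR")
    xfac <- if (is.null(xf)) 1 else as.numeric(xf)
    yfac <- if (is.null(yf)) 1 else as.numeric(yf)
    fx <- getv("FIRSTX"); lx <- getv("LASTX")
    if (is.null(fx) || is.null(lx))
      stop("JCAMP-DX: XYDATA record lacks ##FIRSTX/##LASTX; cannot build ",
           "the ppm axis")
    xfirst <- as.numeric(fx) * xfac
    xlast <- as.numeric(lx) * xfac
    xy <- Filter(function(b) b$kind == "XYDATA", blocks)
    re <- decode_tabular_block(xy[[1L]]$lines) * yfac
    if (length(xy) >= 2L) im <- decode_tabular_block(xy[[2L]]$lines) * yfac
  }

  if (is.null(re))
    stop("JCAMP-DX: no real-channel data found in ", path)
  if (is.null(im))
    stop("JCAMP-DX: no imaginary channel found in ", path,
         "; phase correction requires complex (real + imaginary) data")
  if (length(re) != length(im))
    stop("JCAMP-DX: real and imaginary traces have different lengths (",
         length(re), " vs ", length(im), ")")
  np <- getv("NPOINTS")
  if (!is.null(np) && as.integer(np) != length(re))
    stop("JCAMP-DX: ##NPOINTS= ", np, " but ", length(re),
         " ordinates were decoded")
  ppm <- seq(xfirst, xlast, length.out = length(re))
  nmr_spectrum(ppm, complex(real = re, imaginary = im),
               meta = list(source = path,
                           title = if (is.null(title)) NA_character_
                                   else title))
}
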