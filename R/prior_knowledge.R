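pk_fields <- c("amplitude", "chemicalshift", "linewidth", "phase", "g")

# Normalize a spreadsheet cell: trim whitespace, map Unicode minus (and the
# en dash some exports produce) to an ASCII hyphen.
normalize_cell <- function(x) {
  x <- gsub("−|–", "-", as.character(x))
  trimws(x)
}

as_number <- function(x) {
  suppressWarnings(as.numeric(normalize_cell(x)))
}

#' Parse one bound cell of a prior-knowledge spreadsheet
#'
#' Bounds use bracket syntax: `"(lo, hi)"` is a range, a single bound with an
#' open bracket defines only one limit — `"(lo,"` means greater than `lo`
#' with no upper limit, `"hi)"` or `"(, hi)"` means less than `hi` with no
#' lower limit — and a bare number fixes the parameter at that value. ASCII
#' hyphens and Unicode minus signs are both accepted.
#'
#' @param cell_text The cell contents.
#' @param where Optional label (row/column) used in error messages.
#' @return A list with elements `type` (`"range"` or `"fixed"`), `lower`,
#'   `upper` (possibly infinite) and `fixed`.
#' @export
#' @examples
#' parse_bound("(-180, 180)")
#' parse_bound("(0,")
#' parse_bound("0")
parse_bound <- function(cell_text, where = NULL) {
  txt <- normalize_cell(cell_text)
  ctx <- if (is.null(where)) "" else paste0(" at ", where)
  if (!nzchar(txt)) stop("empty bound cell", ctx)
  fail <- function() stop(sprintf("malformed bound '%s'%s", cell_text, ctx))
  num_or <- function(s, default) {
    s <- trimws(s)
    if (!nzchar(s)) return(default)
    v <- as_number(s)
    if (is.na(v)) fail()
    v
  }
  if (grepl("^\\(", txt) && grepl("\\)$", txt)) {
    body <- sub("^\\(", "", sub("\\)$", "", txt))
    parts <- strsplit(body, ",", fixed = TRUE)[[1]]
    if (length(parts) > 2) fail()
    if (length(parts) == 1) parts <- c(parts, "")
    if (!grepl(",", body, fixed = TRUE)) fail()
    lower <- num_or(parts[1], -Inf)
    upper <- num_or(parts[2], Inf)
    if (!(lower < upper)) stop(sprintf("bound '%s'%s has lower >= upper", cell_text, ctx))
    return(list(type = "range", lower = lower, upper = upper, fixed = NULL))
  }
  if (grepl("^\\(", txt)) {                     # "(lo," : lower limit only
    body <- sub("^\\(", "", sub(",$", "", txt))
    lower <- num_or(body, NA)
    if (is.na(lower)) fail()
    return(list(type = "range", lower = lower, upper = Inf, fixed = NULL))
  }
  if (grepl("\\)$", txt)) {                     # "hi)" or ", hi)" : upper only
    body <- sub("\\)$", "", txt)
    body <- sub("^,", "", body)
    upper <- num_or(body, NA)
    if (is.na(upper)) fail()
    return(list(type = "range", lower = -Inf, upper = upper, fixed = NULL))
  }
  v <- as_number(txt)
  if (is.na(v)) fail()
  list(type = "fixed", lower = v, upper = v, fixed = v)
}

#' Parse one initial-value cell: a number or a tie expression
#'
#' Tie expressions reference a peak already parsed (i.e. placed to the left in
#' the spreadsheet) and always refer to the same parameter row: `"NAME"` ties
#' identically, `"NAME/c"` and `"NAME*c"` tie by an amplitude-style ratio,
#' `"NAME-15Hz"` / `"NAME+15Hz"` offset a chemical shift by a J-coupling
#' splitting in Hz (converted to ppm through the spectrometer frequency when
#' applied), and an unsuffixed `"NAME±c"` in the chemical-shift row is a ppm
#' offset. Only a single binary operation per cell is supported.
#'
#' @param cell_text The cell contents.
#' @param column_field Which parameter row the cell sits in (one of
#'   amplitude, chemicalshift, linewidth, phase, g).
#' @param known_peaks Peaks parsed so far (to the left).
#' @param where Optional label used in error messages.
#' @return A numeric value, or a list of class `amares_expr` with elements
#'   `ref`, `field`, `op` (`identity`, `scale`, `offset_hz`, `offset_ppm`),
#'   `operand` and the original `text`.
#' @export
#' @examples
#' parse_expression("BATP/2", "amplitude", "BATP")
#' parse_expression("BATP-15Hz", "chemicalshift", "BATP")
parse_expression <- function(cell_text, column_field, known_peaks,
                             where = NULL) {
  txt <- gsub("[[:space:]]", "", normalize_cell(cell_text))
  ctx <- if (is.null(where)) "" else paste0(" at ", where)
  if (!nzchar(txt)) stop("empty initial-value cell", ctx)
  v <- as_number(txt)
  if (!is.na(v)) return(v)

  name_re <- "[A-Za-z]+[0-9]*"
  num_re <- "-?[0-9]*\\.?[0-9]+"
  mk <- function(ref, op, operand) {
    if (!grepl(sprintf("^%s$", name_re), ref)) {
      stop(sprintf("invalid peak name '%s' in expression '%s'%s (digits are only permitted as a trailing multiplet index)",
                   ref, cell_text, ctx))
    }
    if (!ref %in% known_peaks) {
      stop(sprintf("expression '%s'%s references peak '%s', which must precede the dependent peak in the spreadsheet",
                   cell_text, ctx, ref))
    }
    structure(list(ref = ref, field = column_field, op = op,
                   operand = operand, text = normalize_cell(cell_text)),
              class = "amares_expr")
  }

  if (grepl(sprintf("^(%s)$", name_re), txt)) {
    return(mk(txt, "identity", NA_real_))
  }
  m <- regmatches(txt, regexec(sprintf("^(%s)([*/])(%s)$", name_re, num_re), txt))[[1]]
  if (length(m)) {
    c0 <- as.numeric(m[4])
    if (c0 == 0 && m[3] == "/") stop(sprintf("division by zero in '%s'%s", cell_text, ctx))
    return(mk(m[2], "scale", if (m[3] == "/") 1 / c0 else c0))
  }
  m <- regmatches(txt, regexec(sprintf("^(%s)([+-])(%s)[Hh]z$", name_re, num_re), txt))[[1]]
  if (length(m)) {
    if (!column_field %in% c("chemicalshift", "linewidth")) {
      stop(sprintf("Hz offset '%s'%s is only supported in the chemicalshift or linewidth row", cell_text, ctx))
    }
    sgn <- if (m[3] == "-") -1 else 1
    return(mk(m[2], "offset_hz", sgn * as.numeric(m[4])))
  }
  m <- regmatches(txt, regexec(sprintf("^(%s)([+-])(%s)$", name_re, num_re), txt))[[1]]
  if (length(m)) {
    if (column_field != "chemicalshift") {
      stop(sprintf("unsuffixed offset '%s'%s is only supported in the chemicalshift row (ppm)", cell_text, ctx))
    }
    sgn <- if (m[3] == "-") -1 else 1
    return(mk(m[2], "offset_ppm", sgn * as.numeric(m[4])))
  }
  stop(sprintf("cannot parse cell '%s'%s", cell_text, ctx))
}

# ---- spreadsheet parsing ----------------------------------------------------

read_pk_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("xlsx", "xls")) {
    df <- readxl::read_excel(path, sheet = 1, col_names = FALSE,
                             col_types = "text", .name_repair = "minimal")
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, header = FALSE, colClasses = "character",
                          blank.lines.skip = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  }
  df[] <- lapply(df, function(col) normalize_cell(ifelse(is.na(col), "", col)))
  df
}

#' Parse a prior-knowledge spreadsheet
#'
#' Reads the spreadsheet dialect used to encode AMARES prior knowledge: an
#' `Index` header row naming the peaks (one column per peak, ordered left to
#' right), an `Initial Values` block and a `Bounds` block each holding the
#' five parameter rows `amplitude`, `chemicalshift` (ppm), `linewidth` (Hz),
#' `phase` (degrees) and `g`, and optional comment lines starting with `#`.
#' Initial-value cells are numbers or tie expressions ([parse_expression()]);
#' bound cells use bracket syntax ([parse_bound()]). Peaks that constrain
#' others must be placed to their left. Multiplet groups are derived by
#' stripping the trailing digits reserved for subpeak labels (e.g. `BATP`,
#' `BATP2`, `BATP3` form the `BATP` group).
#'
#' A numeric initial `g` of exactly 0 pins that peak to a Lorentzian
#' lineshape (the parameter is fixed) regardless of the g bounds; a positive
#' initial `g` is fitted within its bounds.
#'
#' @param x Path to a CSV or XLSX file (first sheet used), or a data frame /
#'   matrix of character cells laid out the same way.
#' @param carrier_mhz Spectrometer frequency in MHz, used to convert Hz tie
#'   offsets to ppm.
#' @param ref_ppm Chemical shift at 0 Hz offset (default 0).
#' @return An object of class `prior_knowledge`: peak names in spreadsheet
#'   order, a cell table, multiplet groups, and the acquisition context.
#' @export
#' @examples
#' path <- system.file("extdata", "prior_31p_brain.csv", package = "amaresr")
#' pk <- parse_prior_knowledge(path, carrier_mhz = 120.66)
#' pk
parse_prior_knowledge <- function(x, carrier_mhz, ref_ppm = 0) {
  if (!is.numeric(carrier_mhz) || carrier_mhz <= 0) stop("`carrier_mhz` must be > 0")
  if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) stop("prior-knowledge file not found: ", x)
    df <- read_pk_table(x)
  } else {
    df <- as.data.frame(x, stringsAsFactors = FALSE)
    df[] <- lapply(df, function(col) normalize_cell(ifelse(is.na(col), "", col)))
  }
  # drop comment lines
  df <- df[!grepl("^#", df[[1]]), , drop = FALSE]
  first <- tolower(df[[1]])

  idx_row <- which(first == "index")
  if (length(idx_row) != 1) stop("schema error: expected exactly one 'Index' header row")
  header <- as.character(df[idx_row, -1])
  peaks <- header[nzchar(header)]
  if (length(peaks) == 0) stop("schema error: no peak columns found")
  if (anyDuplicated(peaks)) stop("duplicate peak name: ",
                                 peaks[duplicated(peaks)][1])
  bad <- peaks[!grepl("^[A-Za-z]+[0-9]*$", peaks)]
  if (length(bad)) {
    stop("invalid peak name '", bad[1],
         "': letters with an optional trailing multiplet index only")
  }

  iv_row <- which(first == "initial values")
  bd_row <- which(first == "bounds")
  if (length(iv_row) != 1 || length(bd_row) != 1 || bd_row < iv_row) {
    stop("schema error: expected an 'Initial Values' block followed by a 'Bounds' block")
  }
  take_block <- function(from, to, block) {
    keep <- seq_len(nrow(df)) >= from & seq_len(nrow(df)) <= to
    rows <- df[keep, , drop = FALSE]
    labels <- tolower(rows[[1]])
    out <- list()
    for (f in pk_fields) {
      j <- which(labels == f)
      if (length(j) != 1) {
        stop(sprintf("schema error: %s block must contain exactly one '%s' row", block, f))
      }
      out[[f]] <- as.character(rows[j, 1 + seq_along(peaks)])
    }
    out
  }
  iv <- take_block(iv_row + 1, bd_row - 1, "Initial Values")
  bd <- take_block(bd_row + 1, nrow(df), "Bounds")

  cells <- tidyr::expand_grid(peak = peaks, field = pk_fields)
  inits <- vector("list", nrow(cells)); bounds <- vector("list", nrow(cells))
  init_text <- character(nrow(cells)); bound_text <- character(nrow(cells))
  for (r in seq_len(nrow(cells))) {
    p <- cells$peak[r]; f <- cells$field[r]
    j <- match(p, peaks)
    where <- sprintf("row '%s', column '%s'", f, p)
    itxt <- iv[[f]][j]
    known <- peaks[seq_len(j - 1)]
    inits[[r]] <- parse_expression(itxt, f, known, where = where)
    init_text[r] <- normalize_cell(itxt)
    btxt <- bd[[f]][j]
    if (is.na(btxt) || !nzchar(normalize_cell(btxt))) {
      bounds[r] <- list(NULL)
      bound_text[r] <- ""
    } else {
      if (grepl("[A-Za-z]", gsub("[Hh]z", "", btxt))) {
        stop(sprintf("expressions are not supported in the Bounds block (%s)", where))
      }
      bounds[[r]] <- parse_bound(btxt, where = where)
      bound_text[r] <- normalize_cell(btxt)
    }
  }
  cells$init <- inits; cells$bound <- bounds
  cells$init_text <- init_text; cells$bound_text <- bound_text

  roots <- sub("[0-9]+$", "", peaks)
  groups <- split(peaks, factor(roots, levels = unique(roots)))

  structure(
    list(peaks = peaks, cells = cells, groups = groups,
         carrier_mhz = carrier_mhz, ref_ppm = ref_ppm),
    class = "prior_knowledge"
  )
}

#' @export
print.prior_knowledge <- function(x, ...) {
  cat(sprintf("<prior_knowledge> %d peaks (%s) | %d multiplet group(s) | carrier %.6g MHz, ref %.6g ppm\n",
              length(x$peaks), paste(x$peaks, collapse = ", "),
              length(x$groups), x$carrier_mhz, x$ref_ppm))
  invisible(x)
}

#' Serialize prior knowledge back to the spreadsheet dialect
#'
#' Writes the same `Index` / `Initial Values` / `Bounds` layout that
#' [parse_prior_knowledge()] reads, preserving the original cell text of ties
#' and bounds, so that parsing the output yields an identical structure.
#'
#' @param pk A `prior_knowledge` object.
#' @param path Optional CSV path to write to.
#' @return The character data frame of cells (invisibly when `path` given).
#' @export
write_prior_knowledge <- function(pk, path = NULL) {
  stopifnot(inherits(pk, "prior_knowledge"))
  cell_of <- function(p, f, what) {
    r <- which(pk$cells$peak == p & pk$cells$field == f)
    pk$cells[[what]][r]
  }
  rows <- list(c("Index", pk$peaks), c("Initial Values", rep("", length(pk$peaks))))
  for (f in pk_fields) {
    rows[[length(rows) + 1]] <- c(f, vapply(pk$peaks, cell_of, "", f = f, what = "init_text"))
  }
  rows[[length(rows) + 1]] <- c("Bounds", rep("", length(pk$peaks)))
  for (f in pk_fields) {
    rows[[length(rows) + 1]] <- c(f, vapply(pk$peaks, cell_of, "", f = f, what = "bound_text"))
  }
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = ",", row.names = FALSE, col.names = FALSE,
                       qmethod = "double", fileEncoding = "UTF-8")
    return(invisible(df))
  }
  df
}
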