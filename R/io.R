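# Spot-table readers/writers: a simple CSV schema and a minimal
# GenePix-results-like tab-separated dialect. Numbers are serialized with
# %.17g so write -> read round-trips are bit-exact.

.spot_cols <- c("block", "row", "column", "id", "conc", "replicate",
                "dilution", "channel", "rfi")

.fmt_num <- function(x) sprintf("%.17g", x)

.as_spot_table <- function(df) {
  df <- df[, .spot_cols]
  key <- paste(df$conc, df$replicate, df$dilution, df$channel, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate spot key (conc, replicate, dilution, channel) at row(s): ",
         paste(utils::head(which(duplicated(key)), 5), collapse = ", "))
  }
  if (any(df$rfi < 0)) stop("raw RFI must be >= 0")
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Write a spot table to disk
#'
#' @param spots a \code{spot_table} data frame.
#' @param path output file path.
#' @param format \code{"csv"} for the simple CSV schema (one row per spot,
#'   all metadata columns explicit) or \code{"gpr"} for a minimal
#'   GenePix-results-like tab-separated dialect: an ATF-style header block
#'   carrying the dilution series, antigen concentrations and
#'   channel-to-intensity-column map, followed by \code{Block}, \code{Row},
#'   \code{Column}, \code{ID} and one median-intensity column per channel.
#'   In the dialect each block is one serum dilution, the column index is
#'   the antigen concentration rank and the row is the replicate.
#' @return \code{path}, invisibly.
#' @export
write_spot_table <- function(spots, path, format = c("csv", "gpr")) {
  format <- match.arg(format)
  stopifnot(is.data.frame(spots), all(.spot_cols %in% names(spots)))
  if (format == "csv") {
    df <- spots[, .spot_cols]
    for (cc in c("conc", "dilution", "rfi")) df[[cc]] <- .fmt_num(df[[cc]])
    utils::write.table(df, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
    return(invisible(path))
  }
  # gpr dialect
  channels <- unique(spots$channel)
  wavelengths <- c(635, 532, 594, 488, 649)
  icols <- sprintf("F%d Median",
                   wavelengths[seq_along(channels) %% length(wavelengths) + 1])
  concs <- sort(unique(spots$conc), decreasing = TRUE)
  zs <- sort(unique(spots$dilution))
  hdr <- c(
    "ATF\t1.0",
    "5\t?",  # placeholder, fixed below
    "\"Type=GenePix Results 3 (microspotr dialect)\"",
    sprintf("\"DilutionSeries=%s\"", paste(.fmt_num(zs), collapse = ",")),
    sprintf("\"AntigenConcentrations=%s\"",
            paste(.fmt_num(concs), collapse = ",")),
    sprintf("\"Channels=%s\"",
            paste(sprintf("%s=%s", channels, icols), collapse = ";")))
  ncols <- 4 + length(channels)
  hdr[2] <- sprintf("%d\t%d", length(hdr) - 2L, ncols)
  # wide: one line per spot position, intensity columns per channel
  base <- unique(spots[, c("block", "row", "column", "id")])
  base <- base[order(base$block, base$column, base$row), ]
  lines <- c(hdr, paste(c("Block", "Row", "Column", "ID", icols),
                        collapse = "\t"))
  ints <- matrix("", nrow(base), length(channels))
  for (j in seq_along(channels)) {
    sub <- spots[spots$channel == channels[j], ]
    key <- paste(sub$block, sub$row, sub$column)
    idx <- match(paste(base$block, base$row, base$column), key)
    ints[, j] <- .fmt_num(sub$rfi[idx])
  }
  body <- paste(base$block, base$row, base$column, base$id,
                apply(ints, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Read a spot table from disk
#'
#' Reads the simple CSV schema or the GenePix-like dialect written by
#' [write_spot_table()]. Malformed input is rejected with an error naming
#' the offending column or line.
#'
#' @param path input file path.
#' @param format \code{"csv"} or \code{"gpr"}; default guessed from the
#'   file extension.
#' @param channel_map optional named character vector mapping channel
#'   labels to intensity column names in a gpr file (e.g.
#'   \code{c(IgG = "F635 Median")}); default taken from the file header.
#' @return A \code{spot_table} data frame (see [simulate_experiment()]).
#' @export
read_spot_table <- function(path, format = NULL, channel_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gpr$", path, ignore.case = TRUE)) "gpr" else "csv"
  }
  format <- match.arg(format, c("csv", "gpr"))
  if (format == "csv") .read_spot_csv(path) else .read_spot_gpr(path, channel_map)
}

.read_spot_csv <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) < 2) stop("no records in ", path)
  df <- utils::read.table(text = ln, sep = ",", header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(.spot_cols, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  for (cc in c("block", "row", "column", "conc", "replicate", "dilution",
               "rfi")) {
    val <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(val) & !is.na(df[[cc]]))
    if (length(bad)) {
      stop(sprintf("unparseable number in column '%s' at line(s): %s",
                   cc, paste(bad + 1L, collapse = ", ")))
    }
    df[[cc]] <- val
  }
  .as_spot_table(df)
}

.read_spot_gpr <- function(path, channel_map = NULL) {
  ln <- readLines(path)
  if (length(ln) < 3 || !startsWith(ln[1], "ATF"))
    stop("not an ATF/GPR-dialect file (no ATF header): ", path)
  counts <- strsplit(ln[2], "\t")[[1]]
  n_hdr <- as.integer(counts[1])
  hdr <- gsub('^"|"$', "", ln[2 + seq_len(n_hdr)])
  get_field <- function(key) {
    hit <- grep(paste0("^", key, "="), hdr, value = TRUE)
    if (!length(hit)) stop("gpr header missing field: ", key)
    sub(paste0("^", key, "="), "", hit[1])
  }
  zs <- as.numeric(strsplit(get_field("DilutionSeries"), ",")[[1]])
  concs <- as.numeric(strsplit(get_field("AntigenConcentrations"), ",")[[1]])
  if (is.null(channel_map)) {
    pairs <- strsplit(strsplit(get_field("Channels"), ";")[[1]], "=")
    channel_map <- stats::setNames(vapply(pairs, `[`, "", 2),
                                   vapply(pairs, `[`, "", 1))
  }
  body <- ln[-(seq_len(2 + n_hdr))]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("no records in ", path)
  tab <- utils::read.table(text = body, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  for (req in c("Block", "Row", "Column", "ID"))
    if (!req %in% names(tab)) stop("missing column(s): ", req)
  bad_icol <- setdiff(unname(channel_map), names(tab))
  if (length(bad_icol))
    stop("missing column(s): ", paste(bad_icol, collapse = ", "))
  out <- do.call(rbind, lapply(names(channel_map), function(ch) {
    data.frame(block = tab$Block, row = tab$Row, column = tab$Column,
               id = tab$ID,
               conc = concs[tab$Column],
               replicate = tab$Row,
               dilution = zs[tab$Block],
               channel = ch,
               rfi = tab[[channel_map[[ch]]]],
               stringsAsFactors = FALSE)
  }))
  if (any(!is.finite(out$conc)))
    stop("column index outside the AntigenConcentrations header series")
  if (any(!is.finite(out$dilution)))
    stop("block index outside the DilutionSeries header series")
  .as_spot_table(out)
}
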