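#' Reduce a spot table to the fitting grid
#'
#' Implements the standard reduction of spot-level microarray records:
#' per (antigen concentration, dilution, channel) cell, replicate RFIs are
#' averaged on the linear scale; per (dilution, channel), the mean RFI of
#' the lowest-concentration cell (the serum-specific background spots) is
#' subtracted from every cell; the background cell itself is flagged
#' excluded; the remaining positive values are log-transformed. Cells
#' whose background-subtracted mean is not positive cannot be
#' log-transformed and are dropped (not floored), with the count reported
#' via \code{message()} and recorded in the \code{"n_dropped"} attribute.
#'
#' @param spots a \code{spot_table} data frame (from
#'   [simulate_experiment()] or [read_spot_table()]).
#' @return A \code{binding_table} data frame with one row per retained
#'   (concentration, dilution, channel) cell: \code{x} (ln molar antigen
#'   concentration), \code{z} (fold-dilution), \code{channel},
#'   \code{ln_signal}, \code{n_used} (replicates averaged),
#'   \code{excluded} (TRUE for the background row, whose \code{ln_signal}
#'   is \code{NA}). Attributes: \code{n_dropped}, \code{background} (data
#'   frame of per-(dilution, channel) background mean and sd of the
#'   background spot RFIs).
#' @export
aggregate_replicates <- function(spots) {
  stopifnot(is.data.frame(spots))
  need <- c("conc", "replicate", "dilution", "channel", "rfi")
  missing_cols <- setdiff(need, names(spots))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(spots) == 0) stop("no records")

  conc_min <- min(spots$conc)
  agg <- stats::aggregate(rfi ~ conc + dilution + channel, data = spots,
                          FUN = mean)
  cnt <- stats::aggregate(rfi ~ conc + dilution + channel, data = spots,
                          FUN = length)
  names(cnt)[names(cnt) == "rfi"] <- "n_used"
  agg <- merge(agg, cnt, by = c("conc", "dilution", "channel"))

  bg_sd <- stats::aggregate(rfi ~ dilution + channel,
                            data = spots[spots$conc == conc_min, ],
                            FUN = stats::sd)
  names(bg_sd)[names(bg_sd) == "rfi"] <- "bg_sd"

  out <- NULL
  n_dropped <- 0L
  for (ch in unique(agg$channel)) {
    for (z in unique(agg$dilution[agg$channel == ch])) {
      cell <- agg[agg$channel == ch & agg$dilution == z, ]
      bg_row <- cell$conc == conc_min
      if (!any(bg_row))
        stop(sprintf("no background (lowest-concentration) cell for dilution %g, channel %s",
                     z, ch))
      bg <- cell$rfi[bg_row]
      sub <- cell$rfi - bg
      excluded <- bg_row
      drop <- !excluded & sub <= 0
      n_dropped <- n_dropped + sum(drop)
      keep <- cell[!drop, , drop = FALSE]
      sub <- sub[!drop]
      excl <- excluded[!drop]
      out <- rbind(out, data.frame(
        x = log(keep$conc), z = keep$dilution, channel = keep$channel,
        ln_signal = ifelse(excl, NA_real_, log(pmax(sub, .Machine$double.xmin))),
        n_used = keep$n_used, excluded = excl,
        stringsAsFactors = FALSE))
    }
  }
  out <- out[order(out$channel, out$z, -out$x), ]
  rownames(out) <- NULL
  if (n_dropped > 0)
    message(sprintf("aggregate_replicates: dropped %d cell(s) with non-positive background-subtracted signal",
                    n_dropped))
  if (!any(!out$excluded))
    stop("no fittable data: all values non-positive after background subtraction")
  class(out) <- c("binding_table", "data.frame")
  attr(out, "n_dropped") <- n_dropped
  bg_mean <- agg[agg$conc == conc_min, c("dilution", "channel", "rfi")]
  names(bg_mean)[names(bg_mean) == "rfi"] <- "bg_mean"
  attr(out, "background") <- merge(bg_mean, bg_sd,
                                   by = c("dilution", "channel"),
                                   all.x = TRUE)
  out
}

#' Write / read a binding table as CSV
#'
#' @param tbl a \code{binding_table} from [aggregate_replicates()].
#' @param path file path.
#' @return \code{path} (write) or a \code{binding_table} (read).
#' @export
write_binding_table <- function(tbl, path) {
  df <- as.data.frame(tbl)
  df$x <- .fmt_num(df$x)
  df$z <- .fmt_num(df$z)
  df$ln_signal <- ifelse(is.na(tbl$ln_signal), "NA", .fmt_num(tbl$ln_signal))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_binding_table
#' @export
read_binding_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "z", "channel", "ln_signal", "n_used", "excluded")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  class(df) <- c("binding_table", "data.frame")
  df
}

# rows usable for fitting
.fittable <- function(tbl, channel = NULL) {
  stopifnot(is.data.frame(tbl))
  keep <- !tbl$excluded & is.finite(tbl$ln_signal)
  if (!is.null(channel)) keep <- keep & tbl$channel == channel
  tbl[keep, , drop = FALSE]
}
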