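#' Read a BED3/BED6 file
#'
#' Tab-separated, no header. Lines starting with `#`, `track` or `browser`
#' are skipped. A `.` in the name, score or strand column is read as
#' missing. Coordinates are kept in the file's 0-based half-open
#' convention.
#'
#' @param path File path.
#' @return An interval `data.frame` (see [interval_set()]).
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(complete_intervals(data.frame(chrom = character(),
                                         start = integer(), end = integer(),
                                         stringsAsFactors = FALSE)))
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  out <- data.frame(
    chrom = df[[1]],
    start = as.integer(df[[2]]),
    end = as.integer(df[[3]]),
    stringsAsFactors = FALSE
  )
  out$name <- if (ncol(df) >= 4) ifelse(df[[4]] == ".", NA_character_, df[[4]]) else NA_character_
  out$score <- if (ncol(df) >= 5) suppressWarnings(as.numeric(ifelse(df[[5]] == ".", NA, df[[5]]))) else NA_real_
  out$strand <- if (ncol(df) >= 6) ifelse(df[[6]] %in% c("+", "-"), df[[6]], ".") else "."
  out <- out[, c("chrom", "start", "end", "strand", "score", "name")]
  validate_intervals(out)
  out
}

# Scores are serialised with up to 6 significant digits; round-trips are
# exact for scores representable at that precision.
format_score <- function(s) {
  ifelse(is.na(s), ".", formatC(s, format = "g", digits = 6))
}

#' Write an interval set as BED
#'
#' Writes BED3 when no name/score/strand information is present, BED6
#' otherwise. Missing fields are written as `.`.
#'
#' @param x Interval `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- complete_intervals(x)
  validate_intervals(x)
  bed6 <- any(!is.na(x$name)) || any(!is.na(x$score)) || any(x$strand != ".")
  df <- data.frame(x$chrom, x$start, x$end, stringsAsFactors = FALSE)
  if (bed6) {
    df$name <- ifelse(is.na(x$name), ".", x$name)
    df$score <- format_score(x$score)
    df$strand <- x$strand
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE file (optionally with UMIs)
#'
#' Expects the ten standard columns `chrom1 start1 end1 chrom2 start2 end2
#' name score strand1 strand2`. Unique molecular identifiers are accepted
#' in either dialect: two extra columns (11 and 12), or embedded in the
#' name field as `"UMI1|UMI2"`. Comment lines (`#`, `track`, `browser`)
#' are tolerated.
#'
#' @param path File path.
#' @return A data frame with columns `chrom1,start1,end1,chrom2,start2,
#'   end2,name,score,strand1,strand2,umi1,umi2`.
#' @export
read_bedpe <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  empty <- data.frame(chrom1 = character(), start1 = integer(), end1 = integer(),
                      chrom2 = character(), start2 = integer(), end2 = integer(),
                      name = character(), score = numeric(),
                      strand1 = character(), strand2 = character(),
                      umi1 = character(), umi2 = character(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          colClasses = "character", quote = "",
                          comment.char = "")
  if (ncol(df) < 6) stop("BEDPE requires at least 6 columns")
  pad <- function(i, default) if (ncol(df) >= i) df[[i]] else rep(default, nrow(df))
  out <- data.frame(
    chrom1 = df[[1]], start1 = as.integer(df[[2]]), end1 = as.integer(df[[3]]),
    chrom2 = df[[4]], start2 = as.integer(df[[5]]), end2 = as.integer(df[[6]]),
    name = pad(7, "."), score = suppressWarnings(as.numeric(ifelse(pad(8, ".") == ".", NA, pad(8, ".")))),
    strand1 = pad(9, "."), strand2 = pad(10, "."),
    stringsAsFactors = FALSE
  )
  if (ncol(df) >= 12) {
    out$umi1 <- df[[11]]
    out$umi2 <- df[[12]]
  } else if (any(grepl("\\|", out$name))) {
    parts <- strsplit(out$name, "|", fixed = TRUE)
    out$umi1 <- vapply(parts, function(p) if (length(p) >= 1) p[1] else NA_character_, "")
    out$umi2 <- vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, "")
  } else {
    out$umi1 <- NA_character_
    out$umi2 <- NA_character_
  }
  out
}

#' Write interactions as BEDPE
#'
#' @param x Data frame as returned by [read_bedpe()] or
#'   [simulate_interactions()].
#' @param path Output path.
#' @param umi_columns If `TRUE` (default) UMIs are written as two extra
#'   columns; otherwise they are embedded in the name field as
#'   `"UMI1|UMI2"`.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(x, path, umi_columns = TRUE) {
  df <- data.frame(
    x$chrom1, x$start1, x$end1, x$chrom2, x$start2, x$end2,
    name = if (!is.null(x$name)) ifelse(is.na(x$name), ".", x$name) else ".",
    score = format_score(if (!is.null(x$score)) x$score else NA_real_),
    strand1 = if (!is.null(x$strand1)) x$strand1 else ".",
    strand2 = if (!is.null(x$strand2)) x$strand2 else ".",
    stringsAsFactors = FALSE
  )
  has_umi <- !is.null(x$umi1) && any(!is.na(x$umi1))
  if (has_umi) {
    if (umi_columns) {
      df$umi1 <- x$umi1
      df$umi2 <- x$umi2
    } else {
      df$name <- paste(x$umi1, x$umi2, sep = "|")
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a density track as bedGraph
#'
#' @param chrom Chromosome name (recycled).
#' @param start,end 0-based half-open bin coordinates.
#' @param value Numeric track value per bin.
#' @param path Output path.
#' @param name Track name for the header line.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(chrom, start, end, value, path, name = "track") {
  header <- sprintf("track type=bedGraph name=\"%s\"", name)
  df <- data.frame(chrom, start, end, value, stringsAsFactors = FALSE)
  writeLines(header, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, append = TRUE)
  invisible(path)
}

# Thin TSV helpers used by the analysis drivers and run_pipeline().
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}
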