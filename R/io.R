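#' Read a BED file
#'
#' Reads BED3/BED6 (tab-delimited, 0-based half-open). `track`, `browser`
#' and `#` header lines are tolerated and skipped; any other malformed line
#' raises an error naming its line number.
#'
#' @param path Path to a BED file.
#' @return A sorted interval tibble with whichever of `name`, `score`,
#'   `strand` the file carries.
#' @export
read_bed <- function(path) {
  lines <- readr::read_lines(path)
  parsed <- .parse_bedlike(lines, min_fields = 3, what = "BED", path = path)
  if (nrow(parsed$fields) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer()))
  }
  f <- parsed$fields
  out <- tibble::tibble(chrom = f[[1]],
                        start = .int_field(f[[2]], "start", parsed$lineno, path),
                        end = .int_field(f[[3]], "end", parsed$lineno, path))
  if (ncol(f) >= 4) out$name <- f[[4]]
  if (ncol(f) >= 5) out$score <- suppressWarnings(as.numeric(f[[5]]))
  if (ncol(f) >= 6) out$strand <- f[[6]]
  bad <- which(is.na(out$start) | is.na(out$end) | out$end <= out$start)
  if (length(bad) > 0) {
    stop(glue::glue(
      "{path}: malformed BED interval at line {parsed$lineno[bad[1]]}"),
      call. = FALSE)
  }
  sort_intervals(out)
}

.parse_bedlike <- function(lines, min_fields, what, path) {
  lineno <- seq_along(lines)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- lineno[keep]
  if (length(lines) == 0) {
    return(list(fields = tibble::tibble(), lineno = integer()))
  }
  split_fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(split_fields)
  if (any(nf < min_fields)) {
    bad <- which(nf < min_fields)[1]
    stop(glue::glue(
      "{path}: malformed {what} line {lineno[bad]}: fewer than ",
      "{min_fields} tab-separated fields"), call. = FALSE)
  }
  ncols <- min(nf)
  fields <- tibble::as_tibble(
    as.data.frame(do.call(rbind, lapply(split_fields, `[`, seq_len(ncols))),
                  stringsAsFactors = FALSE),
    .name_repair = "minimal")
  list(fields = fields, lineno = lineno)
}

.int_field <- function(x, field, lineno, path) {
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) {
    bad <- which(is.na(v))[1]
    stop(glue::glue(
      "{path}: malformed {field} at line {lineno[bad]}: '{x[bad]}'"),
      call. = FALSE)
  }
  v
}

#' Write intervals as BED
#'
#' Emits BED3/BED6 depending on which optional columns are present; never
#' writes header lines. Round-trips with [read_bed()].
#'
#' @param x An interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  check_intervals(x)
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(x) || "score" %in% names(x) || "strand" %in% names(x)) {
    x$name <- if ("name" %in% names(x)) x$name else "."
    x$score <- if ("score" %in% names(x)) x$score else 0
    x$strand <- if ("strand" %in% names(x)) x$strand else "."
    cols <- c(cols, "name", "score", "strand")
  }
  readr::write_tsv(as.data.frame(x)[, cols, drop = FALSE], path,
                   col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Four tab-separated columns `chrom start end value`, 0-based half-open
#' steps. Header lines tolerated; malformed lines error with line numbers.
#'
#' @param path Path to a bedGraph file.
#' @return A signal-track tibble (`chrom`, `start`, `end`, `value`).
#' @export
read_bedgraph <- function(path) {
  lines <- readr::read_lines(path)
  parsed <- .parse_bedlike(lines, min_fields = 4, what = "bedGraph",
                           path = path)
  if (nrow(parsed$fields) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), value = numeric()))
  }
  f <- parsed$fields
  out <- tibble::tibble(chrom = f[[1]],
                        start = .int_field(f[[2]], "start", parsed$lineno, path),
                        end = .int_field(f[[3]], "end", parsed$lineno, path),
                        value = suppressWarnings(as.numeric(f[[4]])))
  if (anyNA(out$value)) {
    bad <- which(is.na(out$value))[1]
    stop(glue::glue(
      "{path}: malformed value at line {parsed$lineno[bad]}"), call. = FALSE)
  }
  check_track(out)
  dplyr::arrange(out, .data$chrom, .data$start)
}

#' Write a signal track as bedGraph
#' @param track A signal-track tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  check_track(track)
  readr::write_tsv(as.data.frame(track)[, c("chrom", "start", "end", "value")],
                   path, col_names = FALSE)
  invisible(path)
}

#' Read a FASTA genome
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @return A named character vector of uppercase sequences, one per contig;
#'   names are the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  lines <- readr::read_lines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) {
    stop(glue::glue("{path}: not a FASTA file (no leading '>')"),
         call. = FALSE)
  }
  idx <- cumsum(hdr)
  names_all <- sub("^>(\\S+).*$", "\\1", lines[hdr])
  seqs <- vapply(split(lines[!hdr], idx[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  out <- character(length(names_all))
  names(out) <- names_all
  out[as.integer(names(seqs))] <- seqs
  names(out) <- names_all
  out
}

#' Write a FASTA genome
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome)) {
    writeLines(paste0(">", nm), con)
    s <- genome[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Reverse-complement a DNA sequence
#' @param seq Character vector of A/C/G/T/N sequences.
#' @return The reverse complement(s).
#' @export
reverse_complement <- function(seq) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' Extract the sequence of a genomic interval
#'
#' Returns the uppercase sequence of `[start, end)` on `chrom`;
#' minus-strand extraction reverse-complements.
#'
#' @param genome Named character vector, as from [read_fasta()].
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param strand `"+"` (default), `"-"`, or `"."` (treated as `"+"`).
#' @return A character scalar of length `end - start`.
#' @export
#' @examples
#' extract_sequence(c(chr1 = "AACGTT"), "chr1", 2, 5)       # "CGT"
#' extract_sequence(c(chr1 = "AACGTT"), "chr1", 2, 5, "-")  # "ACG"
extract_sequence <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    stop(glue::glue("unknown contig '{chrom}'"), call. = FALSE)
  }
  n <- nchar(genome[[chrom]])
  if (start < 0 || end > n || end <= start) {
    stop(glue::glue(
      "interval {chrom}:{start}-{end} outside contig (length {n})"),
      call. = FALSE)
  }
  s <- substr(genome[[chrom]], start + 1, end)
  if (identical(strand, "-")) s <- reverse_complement(s)
  s
}

#' Read a JASPAR-style PFM library
#'
#' Supports the bracketed dialect
#' (`>ID name` then `A [ 1 2 3 ]` ... for C, G, T) and the bare 4-row
#' numeric dialect (`>ID` then four whitespace-separated count rows in
#' A, C, G, T order). Counts are converted to probabilities with a
#' pseudocount.
#'
#' @param path Path to a PFM file.
#' @param pseudocount Added per cell when converting counts to
#'   probabilities (default 0.01).
#' @return A named list of `pwm` objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.01) {
  lines <- trimws(readr::read_lines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) {
    stop(glue::glue("{path}: no '>' record headers found"), call. = FALSE)
  }
  bounds <- c(hdr, length(lines) + 1L)
  pwms <- list()
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1):(bounds[i + 1] - 1)]
    id <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr[i]])
    if (length(block) < 4) {
      stop(glue::glue("{path}: record '{id}' has fewer than 4 matrix rows"),
           call. = FALSE)
    }
    rows <- lapply(block[1:4], function(l) {
      l <- sub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1) {
      stop(glue::glue("{path}: record '{id}' rows differ in length"),
           call. = FALSE)
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- c("A", "C", "G", "T")
    pwms[[id]] <- pwm_from_counts(counts, id = id, pseudocount = pseudocount)
  }
  pwms
}

#' Write motif occurrences as BED6
#'
#' The score column holds `round(score_ratio * 1000)`, the BED convention
#' for bounded scores.
#'
#' @param occ An occurrence tibble from [scan_pwm()] carrying `chrom`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_occurrences_bed <- function(occ, path) {
  stopifnot(all(c("chrom", "start", "end", "strand", "score_ratio") %in%
                  names(occ)))
  out <- tibble::tibble(chrom = occ$chrom, start = occ$start, end = occ$end,
                        name = if ("pwm" %in% names(occ)) occ$pwm else ".",
                        score = round(occ$score_ratio * 1000),
                        strand = occ$strand)
  write_bed(out, path)
}
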