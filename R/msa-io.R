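# Alignment I/O: A3M (lowercase = insertions relative to the query) and
# aligned FASTA. Normalizes to the MSA representation: uppercase match
# columns, per-position deletion counts, best-effort species labels.

# Split FASTA-like text into headers (without ">") and concatenated
# sequence strings. Errors on empty input or records without sequence.
.split_fasta <- function(text) {
  lines <- strsplit(text, "\r?\n")[[1]]
  lines <- lines[nzchar(lines)]
  if (!length(lines)) .stopf("format error: empty alignment input")
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1]) .stopf("format error: input must start with a '>' header")
  rec <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], rec[!is_hdr]), paste, "", collapse = "")
  if (length(seqs) != length(headers) || any(!nzchar(seqs)))
    .stopf("format error: every record needs at least one sequence line")
  list(headers = headers, seqs = unname(seqs))
}

# Best-effort taxon label from a header: token after "OX=" or "TaxID=".
.parse_species <- function(headers) {
  sp <- rep(NA_character_, length(headers))
  m <- regmatches(headers, regexpr("(OX=|TaxID=)[^[:space:]]+", headers))
  hit <- regexpr("(OX=|TaxID=)[^[:space:]]+", headers) > 0
  sp[hit] <- sub("^(OX=|TaxID=)", "", m)
  sp
}

# Map rare/ambiguity codes to 'X'; '*' terminators and '.' insert padding
# are stripped before any column accounting.
.normalize_chars <- function(chars) {
  up <- toupper(chars)
  up[up %in% c("B", "Z", "J", "U", "O")] <- "X"
  up
}

#' Parse an A3M alignment
#'
#' Lowercase letters denote insertions relative to the query; they are
#' removed from the rows and accumulated into the deletion-count matrix at
#' the match column that follows the insertion run. Ambiguity codes
#' B/Z/J/U/O map to 'X'; '*' terminators and '.' padding are stripped.
#' Species labels are parsed from header tokens `OX=...` or `TaxID=...`
#' when present.
#'
#' @param text A3M-formatted text; the first record is the query.
#' @return An [MSA-class] object.
#' @seealso [writeA3M()], [parseAlignedFasta()]
#' @export
#' @examples
#' msa <- parseA3M(">q\nAC\n>s1 OX=9606\nAaC\n")
#' msaDeletions(msa)[2, ]
parseA3M <- function(text) {
  rec <- .split_fasta(text)
  parsed <- lapply(rec$seqs, function(s) {
    chars <- strsplit(s, "")[[1]]
    chars <- chars[!chars %in% c("*", ".")]
    if (!length(chars)) .stopf("format error: record with no alignment characters")
    low <- chars %in% letters
    idx <- which(!low)
    if (!length(idx)) .stopf("format error: record consists only of insertions")
    cum <- cumsum(low)
    dels <- as.integer(diff(c(0L, cum[idx])))
    row <- .normalize_chars(chars[idx])
    bad <- setdiff(unique(row), .ALPHABET)
    if (length(bad))
      .stopf("format error: characters outside alphabet: %s", paste(bad, collapse = ""))
    list(row = paste(row, collapse = ""), dels = dels)
  })
  lens <- vapply(parsed, function(p) length(p$dels), 0L)
  if (length(unique(lens)) != 1)
    .stopf("format error: rows differ in match-column count (%s)",
           paste(unique(lens), collapse = ", "))
  MSA(rows = vapply(parsed, `[[`, "", "row"),
      deletions = do.call(rbind, lapply(parsed, `[[`, "dels")),
      species = .parse_species(rec$headers),
      headers = rec$headers)
}

#' Parse an aligned FASTA alignment
#'
#' All records must have equal length; the result has an all-zero deletion
#' matrix (plain FASTA carries no insertion information).
#'
#' @param text aligned FASTA text; the first record is the query.
#' @return An [MSA-class] object.
#' @export
parseAlignedFasta <- function(text) {
  rec <- .split_fasta(text)
  rows <- vapply(rec$seqs, function(s) {
    chars <- .normalize_chars(strsplit(s, "")[[1]])
    chars <- chars[chars != "*"]
    bad <- setdiff(unique(chars), .ALPHABET)
    if (length(bad))
      .stopf("format error: characters outside alphabet: %s", paste(bad, collapse = ""))
    paste(chars, collapse = "")
  }, "")
  if (length(unique(nchar(rows))) != 1)
    .stopf("format error: aligned FASTA records differ in length")
  MSA(rows = rows, species = .parse_species(rec$headers), headers = rec$headers)
}

#' Read an alignment file
#'
#' @param path file path.
#' @param format "a3m" (default) or "fasta"; A3M is a superset of aligned
#'   FASTA, so "a3m" is safe for both.
#' @return An [MSA-class] object.
#' @export
readMSA <- function(path, format = c("a3m", "fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) .stopf("cannot read alignment: %s", path)
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  if (format == "a3m") parseA3M(text) else parseAlignedFasta(text)
}

#' Serialize an MSA as A3M text
#'
#' Headers are written verbatim. Insertion runs are reconstructed from the
#' deletion counts as lowercase 'x' characters (the MSA representation keeps
#' insertion counts, not the inserted residue identities), so
#' `parseA3M(writeA3M(msa))` reproduces `msa` exactly in rows, deletions,
#' species and headers.
#'
#' @param msa an [MSA-class].
#' @param path optional file path; when `NULL` the text is returned.
#' @return The A3M text, invisibly when written to a file.
#' @export
writeA3M <- function(msa, path = NULL) {
  rows <- msaRows(msa)
  dels <- msaDeletions(msa)
  out <- character(2L * length(rows))
  for (i in seq_along(rows)) {
    chars <- strsplit(rows[i], "")[[1]]
    ins <- vapply(dels[i, ], function(k) strrep("x", k), "")
    out[2L * i - 1L] <- paste0(">", msaHeaders(msa)[i])
    out[2L * i] <- paste0(ins, chars, collapse = "")
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (is.null(path)) return(text)
  writeLines(text, path, sep = "")
  invisible(text)
}

#' Fraction of matching positions between an aligned row and the query
#'
#' The fraction of non-gap query positions whose characters agree. Used for
#' picking per-species representative rows during pairing and for
#' deduplication.
#'
#' @param row,query aligned strings of equal length.
#' @return A fraction in [0, 1].
#' @export
sequenceIdentity <- function(row, query) {
  if (nchar(row) != nchar(query)) .stopf("sequenceIdentity: length mismatch")
  q <- strsplit(query, "")[[1]]
  r <- strsplit(row, "")[[1]]
  keep <- q != "-"
  if (!any(keep)) return(0)
  mean(r[keep] == q[keep])
}
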