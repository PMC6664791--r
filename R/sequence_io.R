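#' RNA sequence records
#'
#' An `rna_sequence` is a validated record holding a non-empty identifier and
#' a residue string over the RNA alphabet `{A, C, G, U}` (plus, under the
#' `"normalize"` alphabet policy, retained-but-flagged IUPAC ambiguity codes
#' such as `N`, which downstream kmer counting skips). DNA-alphabet input is
#' accepted and always analyzed as RNA: `T` is mapped to `U`.
#'
#' @param id Non-empty character scalar identifier.
#' @param residues Character scalar of residues.
#' @param alphabet_policy `"strict"` (only A/C/G/U allowed after T->U and
#'   upper-casing) or `"normalize"` (IUPAC ambiguity codes retained and
#'   flagged via the `has_ambiguity` attribute).
#' @return An object of class `rna_sequence` with elements `id`, `residues`,
#'   `length` and logical `has_ambiguity`.
#' @examples
#' rna_sequence("x", "ACGT")  # analyzed as ACGU
#' @export
rna_sequence <- function(id, residues, alphabet_policy = c("normalize", "strict")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    stop("rna_sequence: 'id' must be a non-empty string", call. = FALSE)
  }
  if (!is.character(residues) || length(residues) != 1L || is.na(residues)) {
    stop("rna_sequence: 'residues' must be a character scalar", call. = FALSE)
  }
  res <- normalize_residues(residues)
  bad <- which(!strsplit(res, "", fixed = TRUE)[[1]] %in% c("A", "C", "G", "U"))
  if (alphabet_policy == "strict" && length(bad) > 0L) {
    stop(sprintf(
      "alphabet error: record '%s' has non-ACGU residue '%s' at position %d",
      id, substr(res, bad[1], bad[1]), bad[1]
    ), call. = FALSE)
  }
  structure(
    list(id = id, residues = res, length = nchar(res),
         has_ambiguity = length(bad) > 0L),
    class = "rna_sequence"
  )
}

# T->U and upper-casing; idempotent.
normalize_residues <- function(x) {
  chartr("t", "u", chartr("T", "U", toupper(x)))
}

#' @export
print.rna_sequence <- function(x, ...) {
  cat(sprintf("<rna_sequence> %s (%d nt)%s\n", x$id, x$length,
              if (isTRUE(x$has_ambiguity)) " [ambiguity codes]" else ""))
  invisible(x)
}

#' @export
length.rna_sequence <- function(x) x$length

#' Read sequences from a FASTA file
#'
#' Reads a (multi-record) FASTA file into an ordered list of
#' [rna_sequence()] records. Order is preserved. Under the
#' `"normalize"` policy `T` is mapped to `U` and lowercase to uppercase;
#' under `"strict"` any residue outside A/C/G/U (after T->U) is an error
#' naming the record and position.
#'
#' @param path Path to an existing FASTA file.
#' @param alphabet_policy `"normalize"` (default) or `"strict"`.
#' @return List of `rna_sequence`, one per record; empty list for an empty
#'   file.
#' @export
read_fasta <- function(path, alphabet_policy = c("normalize", "strict")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) {
    stop(sprintf("I/O error: no such file: %s", path), call. = FALSE)
  }
  check_fasta_wellformed(path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) return(list())
  ids <- sub("\\s.*$", "", names(set))
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    out[[i]] <- rna_sequence(ids[i], as.character(set[[i]]),
                             alphabet_policy = alphabet_policy)
  }
  out
}

# Line-level sanity check so that parse errors can name the offending line
# (Biostrings' own errors are opaque).
check_fasta_wellformed <- function(path) {
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(invisible(TRUE))
  if (!startsWith(lines[nonempty[1]], ">")) {
    stop(sprintf("FASTA parse error at line %d: expected '>' header, got %s",
                 nonempty[1], shQuote(substr(lines[nonempty[1]], 1, 30))),
         call. = FALSE)
  }
  hdr <- startsWith(lines, ">")
  # a header directly followed by another header or EOF has no sequence
  for (i in which(hdr)) {
    j <- i + 1L
    has_seq <- FALSE
    while (j <= length(lines) && !startsWith(lines[j], ">")) {
      if (nzchar(trimws(lines[j]))) has_seq <- TRUE
      j <- j + 1L
    }
    if (!has_seq) {
      stop(sprintf("FASTA parse error at line %d: header %s has no sequence",
                   i, shQuote(substr(lines[i], 1, 30))), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' Writes records so that `read_fasta(write_fasta(S))` reproduces `S`
#' exactly in ids and residues. Lines are wrapped at 60 columns.
#'
#' @param seqs List of [rna_sequence()] (possibly empty).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.list(seqs))
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop(sprintf("I/O error: cannot write %s: %s", path, conditionMessage(e)),
         call. = FALSE)
  })
  on.exit(close(con))
  for (s in seqs) {
    stopifnot(inherits(s, "rna_sequence"))
    writeLines(paste0(">", s$id), con)
    starts <- seq(1L, max(1L, s$length), by = 60L)
    writeLines(substring(s$residues, starts, pmin(starts + 59L, s$length)), con)
  }
  invisible(path)
}
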