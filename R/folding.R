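#' Folding engine contract
#'
#' A folding engine maps an [rna_sequence()] to a [fold_result()]:
#' a dot-bracket structure aligned to the sequence plus a predicted minimum
#' free energy (PMFE, kcal/mol-scale, `<= 0` whenever at least one base pair
#' is formed). Engines must be deterministic. Three engines are provided:
#'
#' * [baseline_engine()] — internal maximum-weight nested pairing (Nussinov
#'   dynamic program, minimum hairpin loop 3, pair weights GC=3 > AU=2 >
#'   GU=1, energy = minus total weight). Fully offline and deterministic;
#'   a stand-in for a thermodynamic folder, not thermodynamically accurate.
#' * [external_engine()] — subprocess adapter for an installed
#'   thermodynamic folder emitting RNAfold-style output
#'   (`structure (-12.30)` on the line after the sequence).
#' * [stub_engine()] — deterministic lookup table keyed by sequence, for
#'   unit tests.
#'
#' @name folding-engines
NULL

#' Fold result
#'
#' @param structure Dot-bracket string over `(`, `)`, `.`.
#' @param pmfe Predicted minimum free energy (numeric scalar).
#' @param engine_name Name of the engine that produced the result.
#' @return Object of class `fold_result` with fields `structure`, `pmfe`,
#'   `engine`.
#' @export
fold_result <- function(structure, pmfe, engine_name = "unknown") {
  if (!is.character(structure) || length(structure) != 1L) {
    stop("fold_result: structure must be a character scalar", call. = FALSE)
  }
  chars <- strsplit(structure, "", fixed = TRUE)[[1]]
  if (!all(chars %in% c("(", ")", "."))) {
    stop("fold_result: structure contains characters outside (, ), .",
         call. = FALSE)
  }
  depth <- cumsum((chars == "(") - (chars == ")"))
  if (length(depth) && (any(depth < 0) || depth[length(depth)] != 0)) {
    stop("fold_result: unbalanced dot-bracket structure", call. = FALSE)
  }
  npairs <- sum(chars == "(")
  pmfe <- as.numeric(pmfe)
  if (npairs == 0L) pmfe <- 0
  if (npairs > 0L && pmfe > 0) {
    stop("fold_result: pmfe must be <= 0 when pairs are present", call. = FALSE)
  }
  structure(list(structure = structure, pmfe = pmfe, engine = engine_name),
            class = "fold_result")
}

new_engine <- function(name, fold_fun) {
  structure(list(name = name, fold_fun = fold_fun), class = "folding_engine")
}

#' @rdname folding-engines
#' @export
baseline_engine <- function() {
  new_engine("baseline", function(seq) {
    r <- nussinov_fold_cpp(seq$residues)
    fold_result(r$structure, r$score, "baseline")
  })
}

#' @rdname folding-engines
#' @param table Named list mapping residue strings to `list(structure, pmfe)`
#'   entries (or `fold_result` objects).
#' @export
stub_engine <- function(table) {
  stopifnot(is.list(table), !is.null(names(table)))
  new_engine("stub", function(seq) {
    entry <- table[[seq$residues]]
    if (is.null(entry)) {
      stop(sprintf("stub engine: no entry for sequence '%s'", seq$id),
           call. = FALSE)
    }
    if (inherits(entry, "fold_result")) return(entry)
    fold_result(entry[[1]], entry[[2]], "stub")
  })
}

#' @rdname folding-engines
#' @param command Path to the folder executable; it must read a FASTA record
#'   on standard input and print the sequence line followed by
#'   `structure (energy)`.
#' @param args Extra command-line arguments.
#' @export
external_engine <- function(command = "RNAfold", args = "--noPS") {
  force(command); force(args)
  new_engine(paste0("external:", basename(command)), function(seq) {
    input <- paste0(">", seq$id, "\n", seq$residues, "\n")
    out <- tryCatch(
      suppressWarnings(system2(command, args, input = input,
                               stdout = TRUE, stderr = TRUE)),
      error = function(e) {
        stop(sprintf("engine error: cannot run '%s': %s", command,
                     conditionMessage(e)), call. = FALSE)
      })
    status <- attr(out, "status")
    if (!is.null(status) && status != 0) {
      stop(sprintf("engine error: '%s' exited with status %d; output:\n%s",
                   command, status, paste(out, collapse = "\n")), call. = FALSE)
    }
    parse_fold_output(out, seq, basename(command))
  })
}

# Parses RNAfold-style output: a line holding dot-bracket + "( energy )" at
# the end. Tolerates UNAfold-style variants where the energy is labelled
# (e.g. "dG = -12.3") on a preceding line.
parse_fold_output <- function(lines, seq, engine_name) {
  pat <- "^([().]+)\\s+\\(\\s*(-?[0-9.]+)\\s*\\)\\s*$"
  hit <- grep(pat, lines, value = TRUE)
  if (length(hit) > 0L) {
    m <- regmatches(hit[1], regexec(pat, hit[1]))[[1]]
    db <- m[2]
    en <- as.numeric(m[3])
  } else {
    db_lines <- grep("^[().]+$", lines, value = TRUE)
    en_lines <- regmatches(lines, regexpr("dG\\s*=\\s*-?[0-9.]+", lines))
    en_lines <- unlist(en_lines)
    if (length(db_lines) == 0L || length(en_lines) == 0L) {
      stop(sprintf("engine error: unparseable output from %s:\n%s",
                   engine_name, paste(lines, collapse = "\n")), call. = FALSE)
    }
    db <- db_lines[1]
    en <- as.numeric(sub(".*=\\s*", "", en_lines[1]))
  }
  if (nchar(db) != seq$length) {
    stop(sprintf(
      "engine error: structure length %d != sequence length %d for '%s'",
      nchar(db), seq$length, seq$id), call. = FALSE)
  }
  fold_result(db, en, paste0("external:", engine_name))
}

#' Predict the secondary structure of a sequence
#'
#' @param seq An [rna_sequence()] over A/C/G/U.
#' @param engine A folding engine (see [folding-engines]); defaults to the
#'   internal baseline engine.
#' @return A [fold_result()] whose structure is aligned to `seq` and whose
#'   `engine` field records the engine used.
#' @export
fold <- function(seq, engine = baseline_engine()) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(engine, "folding_engine"))
  if (isTRUE(seq$has_ambiguity)) {
    stop(sprintf("fold: sequence '%s' contains non-ACGU residues", seq$id),
         call. = FALSE)
  }
  res <- engine$fold_fun(seq)
  if (nchar(res$structure) != seq$length) {
    stop(sprintf("engine error: structure/sequence length mismatch for '%s'",
                 seq$id), call. = FALSE)
  }
  res
}
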