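# Sequence-structure features: triplet encoding of the local pairing
# context, exact dinucleotide-preserving (Euler) shuffling, and the Q_MFE
# permutation statistic.

# evaluate `code` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards. seed = NULL uses the current
# RNG stream unchanged.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# the 8 pairing states of three adjacent bases, in the conventional listing
TRIPLET_STATES <- c("(((", "((.", "(..", "(.(", ".((", ".(.", "..(", "...")

triplet_names <- function() {
  as.vector(t(outer(c("A", "C", "G", "U"), TRIPLET_STATES, paste0)))
}

#' Triplet (sequence-structure hybrid) features
#'
#' Each position of a folded sequence is reduced to paired/unpaired by
#' mapping `)` to `(`. For every center position `i` in `2..L-1` the state
#' triple `(state[i-1], state[i], state[i+1])` is combined with the central
#' base, giving 8 structural states x 4 bases = 32 features, named e.g.
#' `"A((("`. Counts are normalized by the total number of triplets
#' (`L - 2`), so the 32 entries sum to 1.
#'
#' @param seq An [rna_sequence()] of length >= 3.
#' @param fold A [fold_result()] aligned to `seq`.
#' @return Named numeric vector of length 32.
#' @export
triplet_features <- function(seq, fold) {
  stopifnot(inherits(seq, "rna_sequence"), inherits(fold, "fold_result"))
  L <- seq$length
  if (L < 3L) {
    stop(sprintf("degenerate input: sequence '%s' too short for triplets",
                 seq$id), call. = FALSE)
  }
  if (nchar(fold$structure) != L) {
    stop("triplet_features: fold not aligned to sequence", call. = FALSE)
  }
  state <- chartr(")", "(", fold$structure)
  centers <- 2:(L - 1L)
  tri <- substring(state, centers - 1L, centers + 1L)
  base <- substring(seq$residues, centers, centers)
  keys <- paste0(base, tri)
  counts <- table(factor(keys, levels = triplet_names()))
  stats::setNames(as.numeric(counts) / (L - 2L), triplet_names())
}

#' Dinucleotide-preserving Euler shuffle
#'
#' Randomizes a sequence while preserving its exact dinucleotide
#' composition: the output has the same length, the same mononucleotide
#' counts, the same multiset of all 16 ordered dinucleotides, and the same
#' first and last residue (an Euler-path property). The shuffle walks a
#' random Eulerian path on the dinucleotide transition multigraph: random
#' last-exit edges are drawn until they form an arborescence toward the
#' final residue, the remaining out-edges are randomly ordered, and the
#' path is read off.
#'
#' @param seq An [rna_sequence()] over A/C/G/U, length >= 2.
#' @param rng_seed Integer seed for reproducibility, or `NULL` to draw from
#'   the current RNG stream.
#' @return A new [rna_sequence()] with id `<id>_shuf`.
#' @export
dinucleotide_shuffle <- function(seq, rng_seed = NULL) {
  stopifnot(inherits(seq, "rna_sequence"))
  if (seq$length < 2L) {
    stop("degenerate input: need length >= 2 to shuffle dinucleotides",
         call. = FALSE)
  }
  if (isTRUE(seq$has_ambiguity)) {
    stop(sprintf("dinucleotide_shuffle: '%s' contains non-ACGU residues",
                 seq$id), call. = FALSE)
  }
  chars <- strsplit(seq$residues, "", fixed = TRUE)[[1]]
  out <- with_seed(rng_seed, euler_shuffle_chars(chars))
  rna_sequence(paste0(seq$id, "_shuf"), paste(out, collapse = ""))
}

euler_shuffle_chars <- function(chars) {
  n <- length(chars)
  verts <- unique(chars)
  if (length(verts) == 1L) return(chars)
  from <- chars[-n]
  to <- chars[-1L]
  z <- chars[n]
  adj <- split(to, factor(from, levels = verts))
  sources <- verts[vapply(adj, length, 1L) > 0L]

  # draw random last-exit edges until they form an arborescence toward z
  repeat {
    last_edge <- vapply(sources, function(v) {
      outs <- adj[[v]]
      outs[sample.int(length(outs), 1L)]
    }, character(1))
    names(last_edge) <- sources
    ok <- TRUE
    for (v in setdiff(sources, z)) {
      cur <- v
      for (step in seq_len(length(verts) + 1L)) {
        if (cur == z) break
        if (!cur %in% names(last_edge)) { cur <- NA_character_; break }
        cur <- unname(last_edge[[cur]])
      }
      if (is.na(cur) || cur != z) { ok <- FALSE; break }
    }
    if (ok) break
  }

  # per-vertex edge order: random permutation of the non-last edges, then
  # the reserved last edge; the terminal vertex keeps all edges shuffled
  edge_order <- lapply(verts, function(v) {
    outs <- adj[[v]]
    if (length(outs) == 0L) return(character(0))
    if (v == z || !v %in% names(last_edge)) {
      return(outs[sample.int(length(outs))])
    }
    le <- last_edge[[v]]
    idx <- which(outs == le)[1]
    rest <- outs[-idx]
    if (length(rest) > 1L) rest <- rest[sample.int(length(rest))]
    c(rest, le)
  })
  names(edge_order) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)

  out <- character(n)
  out[1] <- chars[1]
  cur <- chars[1]
  for (i in 2:n) {
    nxt <- edge_order[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  out
}

#' Q_MFE permutation statistic
#'
#' Compares a sequence's predicted minimum free energy (PMFE) to the PMFE
#' distribution of `N` dinucleotide-preserving shuffles of itself. With `n`
#' the number of shuffles whose PMFE is less than or equal to the original
#' (ties count toward `n`),
#' \deqn{Q_{MFE} = n / (N + 1).}
#' Low values indicate more predicted structure than expected by chance.
#' Engine failure on any shuffle is an error; `N` is exact, never silently
#' reduced.
#'
#' @param seq An [rna_sequence()].
#' @param N Number of shuffles (default 2000).
#' @param engine Folding engine (see [folding-engines]).
#' @param rng_seed Integer seed; shuffles are drawn from one seeded stream.
#' @return Object of class `qmfe_result` with fields `pmfe_original`, `N`,
#'   `n`, `qmfe`, `engine`.
#' @export
qmfe <- function(seq, N = 2000L, engine = baseline_engine(), rng_seed = NULL) {
  stopifnot(inherits(seq, "rna_sequence"))
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("qmfe: N must be >= 1", call. = FALSE)
  orig <- fold(seq, engine)
  null_pmfe <- with_seed(rng_seed, vapply(seq_len(N), function(i) {
    fold(dinucleotide_shuffle(seq, rng_seed = NULL), engine)$pmfe
  }, numeric(1)))
  # exact comparison on engine-reported values: ties arise from identical
  # shuffles or engine quantization, not float noise
  n <- sum(null_pmfe <= orig$pmfe)
  structure(list(pmfe_original = orig$pmfe, N = N, n = n,
                 qmfe = n / (N + 1), engine = orig$engine),
            class = "qmfe_result")
}

#' @export
print.qmfe_result <- function(x, ...) {
  cat(sprintf("<qmfe_result> PMFE = %.3f, n = %d / N = %d, Q_MFE = %.4f (%s)\n",
              x$pmfe_original, x$n, x$N, x$qmfe, x$engine))
  invisible(x)
}

#' Combined structural feature vector
#'
#' Concatenates the 32 triplet features of the folded sequence with the
#' Q_MFE statistic (feature `"QMFE"`), giving exactly 33 named entries.
#'
#' @inheritParams qmfe
#' @return Named numeric vector of length 33.
#' @export
structural_feature_vector <- function(seq, engine = baseline_engine(),
                                      N = 2000L, rng_seed = NULL) {
  fr <- fold(seq, engine)
  tri <- triplet_features(seq, fr)
  q <- qmfe(seq, N = N, engine = engine, rng_seed = rng_seed)
  c(tri, QMFE = q$qmfe)
}
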