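# shared fixtures and independent oracles

random_rna <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

random_rna_seq <- function(id, n, ...) rna_sequence(id, random_rna(n, ...))

# naive overlap-counting oracle for kmer counts
naive_kmer_count <- function(residues, word) {
  k <- nchar(word)
  L <- nchar(residues)
  if (L < k) return(0L)
  sum(vapply(seq_len(L - k + 1L), function(i)
    substr(residues, i, i + k - 1L) == word, logical(1)))
}

# ordered dinucleotide count vector (16 entries, AA..UU)
dinuc_counts <- function(residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  pairs <- paste0(ch[-length(ch)], ch[-1])
  lv <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"),
                        function(a, b) paste0(a, b)))
  table(factor(pairs, levels = sort(lv)))
}

# brute-force admissible set for the dinucleotide shuffle: all sequences of
# the same length sharing first residue, last residue and the full ordered
# dinucleotide count vector
admissible_set <- function(residues) {
  L <- nchar(residues)
  stopifnot(L >= 2, L <= 8)
  first <- substr(residues, 1, 1)
  last <- substr(residues, L, L)
  ref <- dinuc_counts(residues)
  if (L == 2) return(residues)
  alph <- c("A", "C", "G", "U")
  interiors <- do.call(expand.grid,
                       c(rep(list(alph), L - 2), stringsAsFactors = FALSE))
  cands <- apply(interiors, 1, function(mid)
    paste0(first, paste(mid, collapse = ""), last))
  cands[vapply(cands, function(s) identical(dinuc_counts(s), ref), logical(1))]
}

# exhaustive-pair-counting AUC oracle
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# enumerate every nested pairing (min hairpin loop 3) of a short sequence
# and return the maximum total pair weight; independent of the DP code path
max_pairing_weight_bruteforce <- function(residues) {
  ch <- strsplit(residues, "", fixed = TRUE)[[1]]
  w <- function(a, b) {
    if ((a == "G" && b == "C") || (a == "C" && b == "G")) return(3)
    if ((a == "A" && b == "U") || (a == "U" && b == "A")) return(2)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(1)
    0
  }
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i + 1, j)  # i unpaired: enumerate the rest
    for (k in seq(i + 4, j)) {
      wk <- w(ch[i], ch[k])
      if (wk > 0) {
        inner <- if (k - 1 >= i + 1) rec(i + 1, k - 1) else 0
        outer <- if (k + 1 <= j) rec(k + 1, j) else 0
        best <- max(best, wk + inner + outer)
      }
    }
    best
  }
  rec(1, length(ch))
}

# parse dot-bracket into a set of pairs (for structural checks)
dotbracket_pairs <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  stack <- integer(0)
  pairs <- list()
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      pairs[[length(pairs) + 1]] <- c(stack[length(stack)], i)
      stack <- stack[-length(stack)]
    }
  }
  pairs
}

# a tiny deterministic trained model fixture on planted-signal data
fixture_model <- function(n_pos = 30, n_neg = 120, nrounds = 60,
                          seed = 101) {
  tab <- generate_synthetic_assay(n_pos, n_neg, rng_seed = seed)
  tab <- assign_labels(tab, quiet = TRUE)
  m <- assemble_features(assay_sequences(tab))
  cfg <- model_config(eta = 0.2, nrounds = nrounds, max_depth = 3,
                      min_child_weight = 2, rng_seed = seed)
  list(model = train_ires_model(m, tab$label, cfg,
                                metadata = list(selection = "global-kmer")),
       matrix = m, table = tab)
}
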