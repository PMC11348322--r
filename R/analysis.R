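# Downstream analyses on pairwise co-condensation score tables:
# membraneless-organelle (MLO) versus random comparisons, scaffold-client
# scoring, proteome-wide pair enumeration, partner counting and quintile
# amino-acid-composition contrasts.

#' Build a symmetric score table
#'
#' Order-free lookup of pairwise co-condensation scores.
#'
#' @param id_a,id_b Character vectors of pair endpoints.
#' @param score Numeric scores in `[0, 1]`.
#' @return Object of class `codroplet_scores`.
#' @export
score_table <- function(id_a, id_b, score) {
  stopifnot(length(id_a) == length(id_b), length(id_a) == length(score))
  if (any(score < 0 | score > 1)) {
    stop("scores must lie in [0, 1]", call. = FALSE)
  }
  m <- canonical_pairs(id_a, id_b)
  key <- paste(m[, 1L], m[, 2L], sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop(sprintf("duplicate score for pair (%s)",
                 gsub("\r", ", ", dup)), call. = FALSE)
  }
  env <- new.env(parent = emptyenv(), size = length(key))
  for (i in seq_along(key)) assign(key[i], score[i], envir = env)
  structure(
    list(env = env, id_a = m[, 1L], id_b = m[, 2L], score = score),
    class = "codroplet_scores"
  )
}

#' Read a score table from CSV
#' @param path CSV with columns `protein_a`, `protein_b`, `score`.
#' @return A [score_table()].
#' @export
read_score_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("protein_a", "protein_b", "score") %in% names(df))) {
    stop(sprintf("'%s' must have columns protein_a, protein_b, score", path),
         call. = FALSE)
  }
  score_table(df$protein_a, df$protein_b, df$score)
}

#' Write a score table to CSV
#' @param scores A [score_table()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(scores, path) {
  utils::write.csv(
    data.frame(protein_a = scores$id_a, protein_b = scores$id_b,
               score = scores$score),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' Look up pair scores (order-free)
#'
#' @param scores A [score_table()].
#' @param id_a,id_b Pair endpoints (vectorised).
#' @param strict Error on a missing pair (default) instead of `NA`.
#' @return Numeric vector of scores.
#' @export
lookup_score <- function(scores, id_a, id_b, strict = TRUE) {
  keys <- pair_key(id_a, id_b)
  out <- vapply(seq_along(keys), function(i) {
    v <- get0(keys[i], envir = scores$env, ifnotfound = NA_real_)
    if (strict && is.na(v)) {
      stop(sprintf("no score for pair (%s, %s)", id_a[i], id_b[i]),
           call. = FALSE)
    }
    v
  }, numeric(1L))
  out
}

#' Enumerate all unordered protein pairs
#'
#' Yields all `n (n - 1) / 2` distinct unordered pairs of a protein list
#' as a chunked stream, so proteome-scale enumerations need not be
#' materialised at once.
#'
#' @param protein_ids Character vector of unique identifiers.
#' @param chunk_size Number of pairs per chunk when materialising.
#' @return List with `count` (exact total) and `chunks()`, a function
#'   returning successive two-column id matrices (`NULL` when done).
#' @export
enumerate_proteome_pairs <- function(protein_ids, chunk_size = 1e6) {
  if (anyDuplicated(protein_ids)) {
    stop("protein ids must be unique", call. = FALSE)
  }
  n <- length(protein_ids)
  count <- n * (n - 1) / 2
  # stream state: current first index i and second index j
  i <- 1L
  j <- 2L
  chunks <- function() {
    if (i >= n) return(NULL)
    out_a <- character(0L)
    out_b <- character(0L)
    while (i < n && length(out_a) < chunk_size) {
      take <- min(n - j + 1L, chunk_size - length(out_a))
      jj <- j:(j + take - 1L)
      out_a <- c(out_a, rep(protein_ids[i], take))
      out_b <- c(out_b, protein_ids[jj])
      j <<- j + take
      if (j > n) {
        i <<- i + 1L
        j <<- i + 1L
      }
    }
    if (!length(out_a)) return(NULL)
    cbind(id_a = out_a, id_b = out_b)
  }
  list(count = count, chunks = chunks, n = n)
}

#' Count high-scoring partners per protein
#'
#' For each protein appearing in the score table, counts the partners
#' whose pair score is strictly above `threshold`.
#'
#' @param scores A [score_table()].
#' @param threshold Score cut-off in `[0, 1]` (default 0.8).
#' @return Named integer vector (protein id -> partner count) covering
#'   every protein in the table.
#' @export
partner_counts <- function(scores, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  ids <- sort(unique(c(scores$id_a, scores$id_b)))
  counts <- stats::setNames(integer(length(ids)), ids)
  hi <- scores$score > threshold
  if (any(hi)) {
    t_a <- table(scores$id_a[hi])
    t_b <- table(scores$id_b[hi])
    counts[names(t_a)] <- counts[names(t_a)] + as.integer(t_a)
    counts[names(t_b)] <- counts[names(t_b)] + as.integer(t_b)
  }
  counts
}

#' Partition proteins into top and bottom partner-count quintiles
#'
#' Sorts proteins by partner count (descending, ties broken by id) and
#' returns the first and last `floor(n/5)` proteins.
#'
#' @param counts Named numeric vector, e.g. from [partner_counts()].
#' @return List with character vectors `top` and `bottom` and the group
#'   size `n_group`.
#' @export
quintile_partition <- function(counts) {
  n <- length(counts)
  if (n < 5L) stop("need at least 5 proteins for quintiles", call. = FALSE)
  k <- n %/% 5L
  ord <- order(-counts, names(counts), method = "radix")
  ids <- names(counts)[ord]
  list(top = ids[seq_len(k)], bottom = ids[(n - k + 1L):n], n_group = k)
}

#' Default amino-acid category map
#'
#' Categories used to annotate composition contrasts: positively charged
#' \{R, K, H\}, negatively charged \{D, E\}, aromatic \{F, W, Y\},
#' disorder-promoting \{G, P, S, A\}, hydrophobic \{L, I, V, M, C\},
#' hydrophilic \{N, Q, T\}.  Configurable; the map covers each of the 20
#' residues exactly once.
#'
#' @return Named character vector mapping residue -> category.
#' @export
aa_categories <- function() {
  c(R = "positively charged", K = "positively charged", H = "positively charged",
    D = "negatively charged", E = "negatively charged",
    F = "aromatic", W = "aromatic", Y = "aromatic",
    G = "disorder-promoting", P = "disorder-promoting",
    S = "disorder-promoting", A = "disorder-promoting",
    L = "hydrophobic", I = "hydrophobic", V = "hydrophobic",
    M = "hydrophobic", C = "hydrophobic",
    N = "hydrophilic", Q = "hydrophilic", T = "hydrophilic")
}

aa_fraction_matrix <- function(sequences) {
  keep <- nchar(sequences) > 0L
  if (any(!keep)) warning(sprintf("skipping %d empty sequence(s)", sum(!keep)))
  sequences <- sequences[keep]
  aa <- Biostrings::AAStringSet(sequences)
  m <- Biostrings::letterFrequency(aa, letters = AA_ALPHABET20)
  m / rowSums(m)
}

#' Amino-acid composition difference between two protein sets
#'
#' Computes per-protein residue fractions, then for each of the 20 amino
#' acids the mean fraction in each set, the difference (A - B), the
#' standard error of the difference
#' (`sqrt(s_A^2 / n_A + s_B^2 / n_B)`), a two-sample Welch test p-value as
#' a significance probe, and the category label.
#'
#' @param sequences_a,sequences_b Character vectors of sequences.
#' @param categories Residue -> category map, see [aa_categories()].
#' @return data.frame with one row per amino acid: `aa`, `mean_a`,
#'   `mean_b`, `difference`, `se`, `p_value`, `category`.
#' @export
composition_difference <- function(sequences_a, sequences_b,
                                   categories = aa_categories()) {
  stopifnot(length(sequences_a) >= 1L, length(sequences_b) >= 1L)
  if (!setequal(names(categories), AA_ALPHABET20)) {
    stop("category map must cover the 20 amino acids exactly once",
         call. = FALSE)
  }
  fa <- aa_fraction_matrix(sequences_a)
  fb <- aa_fraction_matrix(sequences_b)
  n_a <- nrow(fa)
  n_b <- nrow(fb)
  out <- data.frame(
    aa = AA_ALPHABET20,
    mean_a = colMeans(fa)[AA_ALPHABET20],
    mean_b = colMeans(fb)[AA_ALPHABET20],
    stringsAsFactors = FALSE
  )
  out$difference <- out$mean_a - out$mean_b
  va <- apply(fa, 2L, stats::var)[AA_ALPHABET20]
  vb <- apply(fb, 2L, stats::var)[AA_ALPHABET20]
  out$se <- sqrt(va / n_a + vb / n_b)
  out$p_value <- vapply(AA_ALPHABET20, function(a) {
    if (n_a < 2L || n_b < 2L || (va[a] == 0 && vb[a] == 0)) return(NA_real_)
    stats::t.test(fa[, a], fb[, a])$p.value
  }, numeric(1L))
  out$category <- unname(categories[out$aa])
  rownames(out) <- NULL
  out
}

#' Compare within-MLO scores against random same-size protein sets
#'
#' Collects all within-set pairwise scores for the MLO's member proteins
#' and for `k_samples` random subsets of the background pool of the same
#' size (sampled without replacement, seeded), reporting each score list
#' and its median.
#'
#' @param mlo_proteins Character vector of MLO member ids (must be scored).
#' @param background_pool Character vector of candidate ids, larger than
#'   the MLO.
#' @param scores A [score_table()].
#' @param k_samples Number of random sets (default 5).
#' @param seed Integer seed.
#' @return List with `mlo` (list: scores, median) and `random` (list of
#'   `k_samples` such lists).
#' @export
mlo_vs_random <- function(mlo_proteins, background_pool, scores,
                          k_samples = 5L, seed = 1L) {
  stopifnot(length(mlo_proteins) >= 2L, k_samples >= 1L)
  if (length(background_pool) < length(mlo_proteins)) {
    stop("background pool must be at least as large as the MLO", call. = FALSE)
  }
  within_scores <- function(ids) {
    mp <- all_member_pairs(sort(ids))
    lookup_score(scores, mp[, 1L], mp[, 2L])
  }
  mlo_sc <- within_scores(mlo_proteins)
  rand <- with_seed(derive_seed(seed, "mlo-random"), {
    lapply(seq_len(k_samples), function(k) {
      ids <- sample(background_pool, length(mlo_proteins))
      sc <- within_scores(ids)
      list(proteins = ids, scores = sc, median = stats::median(sc))
    })
  })
  list(
    mlo = list(proteins = mlo_proteins, scores = mlo_sc,
               median = stats::median(mlo_sc)),
    random = rand
  )
}

#' Scaffold-client score comparison
#'
#' Mean pairwise score of one scaffold protein against an in-set (e.g.
#' stress-granule components) and an out-set (non-members), with the raw
#' per-pair score lists.
#'
#' @param scaffold_id Scaffold protein id.
#' @param in_set,out_set Character vectors of partner ids.
#' @param scores A [score_table()].
#' @return List with `mean_in`, `mean_out`, `scores_in`, `scores_out`.
#' @export
scaffold_client_scores <- function(scaffold_id, in_set, out_set, scores) {
  stopifnot(length(in_set) >= 1L, length(out_set) >= 1L)
  s_in <- lookup_score(scores, rep(scaffold_id, length(in_set)), in_set)
  s_out <- lookup_score(scores, rep(scaffold_id, length(out_set)), out_set)
  list(mean_in = mean(s_in), mean_out = mean(s_out),
       scores_in = stats::setNames(s_in, in_set),
       scores_out = stats::setNames(s_out, out_set))
}
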