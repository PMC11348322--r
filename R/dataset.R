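# Construction of labelled protein-pair datasets from condensate
# membership tables: within-condensate positives, non-co-occurring
# negatives, self-pair expansion with interaction-network exclusion,
# sequence-identity and length filters, condensate-aware splitting and
# class rebalancing.

#' Build a condensate membership table
#'
#' @param condensate_id Character vector of condensate identifiers.
#' @param protein_id Character vector of member protein identifiers
#'   (parallel to `condensate_id`).
#' @return Object of class `codroplet_condensates`: a named list mapping
#'   condensate id to its set of member protein ids.
#' @export
condensate_table <- function(condensate_id, protein_id) {
  stopifnot(length(condensate_id) == length(protein_id))
  tab <- lapply(split(as.character(protein_id), as.character(condensate_id)),
                function(x) sort(unique(x)))
  if (any(lengths(tab) == 0L)) stop("empty condensate", call. = FALSE)
  structure(tab, class = "codroplet_condensates")
}

#' Read a condensate table from TSV
#'
#' Expects columns `condensate_id` and `protein_id` (an optional
#' `confidence` column is tolerated and ignored).
#'
#' @param path TSV file path.
#' @return A [condensate_table()].
#' @export
read_condensate_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("condensate_id", "protein_id") %in% names(df))) {
    stop(sprintf("'%s' must have columns condensate_id, protein_id", path),
         call. = FALSE)
  }
  condensate_table(df$condensate_id, df$protein_id)
}

#' Read a protein-protein interaction edge list from TSV
#'
#' Expects columns `protein_a` and `protein_b`; edges are undirected.
#'
#' @param path TSV file path.
#' @return data.frame with columns `protein_a`, `protein_b` (canonically
#'   ordered, deduplicated, self-loops dropped).
#' @export
read_ppi <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("protein_a", "protein_b") %in% names(df))) {
    stop(sprintf("'%s' must have columns protein_a, protein_b", path),
         call. = FALSE)
  }
  ppi_network(df$protein_a, df$protein_b)
}

#' Build an undirected PPI network
#' @param protein_a,protein_b Character vectors of edge endpoints.
#' @return data.frame with canonical columns `protein_a`, `protein_b`.
#' @export
ppi_network <- function(protein_a, protein_b) {
  m <- canonical_pairs(protein_a, protein_b)
  keep <- m[, 1L] != m[, 2L]
  m <- m[keep, , drop = FALSE]
  df <- unique(data.frame(protein_a = m[, 1L], protein_b = m[, 2L],
                          stringsAsFactors = FALSE))
  rownames(df) <- NULL
  df
}

ppi_neighbours <- function(ppi, ids) {
  sel_a <- ppi$protein_a %in% ids
  sel_b <- ppi$protein_b %in% ids
  unique(c(ppi$protein_b[sel_a], ppi$protein_a[sel_b]))
}

empty_pairs <- function() {
  data.frame(id_a = character(), id_b = character(), label = integer(),
             sources = character(), is_self_pair = logical(),
             stringsAsFactors = FALSE)
}

make_pairs <- function(id_a, id_b, label, sources = "", is_self_pair = FALSE) {
  if (length(id_a) == 0L) return(empty_pairs())
  m <- canonical_pairs(id_a, id_b)
  data.frame(id_a = m[, 1L], id_b = m[, 2L], label = as.integer(label),
             sources = sources, is_self_pair = is_self_pair,
             stringsAsFactors = FALSE)
}

all_member_pairs <- function(members) {
  k <- length(members)
  if (k < 2L) return(NULL)
  idx <- utils::combn(k, 2L)
  cbind(members[idx[1L, ]], members[idx[2L, ]])
}

#' Build within-condensate positive pairs
#'
#' For each condensate with at most `n_max` members, all unordered member
#' pairs are emitted with label 1.  Pairs occurring in several condensates
#' are deduplicated, with their source condensates unioned
#' (comma-separated in the `sources` column).  Condensates above the cap
#' are skipped (protein components of very large condensates are the least
#' reliable annotations) and reported via a message.
#'
#' @param condensates A [condensate_table()].
#' @param n_max Maximum condensate size to use (default 50).
#' @return Pair data.frame with columns `id_a`, `id_b`, `label`,
#'   `sources`, `is_self_pair`.
#' @export
build_positive_pairs <- function(condensates, n_max = 50L) {
  stopifnot(inherits(condensates, "codroplet_condensates"), n_max >= 2L)
  skipped <- names(condensates)[lengths(condensates) > n_max]
  if (length(skipped)) {
    message(sprintf("skipping %d condensate(s) larger than n_max=%d: %s",
                    length(skipped), n_max, paste(skipped, collapse = ", ")))
  }
  rows <- list()
  for (cid in names(condensates)) {
    members <- condensates[[cid]]
    if (length(members) > n_max) next
    mp <- all_member_pairs(members)
    if (is.null(mp)) next
    rows[[cid]] <- make_pairs(mp[, 1L], mp[, 2L], 1L, sources = cid)
  }
  if (!length(rows)) return(empty_pairs())
  df <- do.call(rbind, rows)
  key <- paste(df$id_a, df$id_b, sep = "\r")
  agg <- tapply(df$sources, key, function(s) paste(sort(unique(s)), collapse = ","))
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$sources <- as.character(agg[paste(out$id_a, out$id_b, sep = "\r")])
  out <- out[order(out$id_a, out$id_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Set of keys of all pairs co-occurring in any condensate (no size cap).
cooccurring_keys <- function(condensates) {
  keys <- character()
  for (members in condensates) {
    mp <- all_member_pairs(members)
    if (!is.null(mp)) keys <- c(keys, pair_key(mp[, 1L], mp[, 2L]))
  }
  unique(keys)
}

#' Build cross-condensate negative pairs
#'
#' Candidate proteins are the members of condensates with at most `m`
#' members.  Every unordered pair of candidates that does not co-occur in
#' any condensate of the full table (regardless of size) is labelled 0.
#'
#' @param condensates A [condensate_table()].
#' @param m Maximum condensate size contributing candidates (default 12).
#' @return Pair data.frame (label 0, empty `sources`).
#' @export
build_negative_pairs <- function(condensates, m = 12L) {
  stopifnot(inherits(condensates, "codroplet_condensates"), m >= 1L)
  cand <- sort(unique(unlist(condensates[lengths(condensates) <= m],
                             use.names = FALSE)))
  if (length(cand) < 2L) return(empty_pairs())
  pos_keys <- cooccurring_keys(condensates)
  mp <- all_member_pairs(cand)
  keep <- !(pair_key(mp[, 1L], mp[, 2L]) %in% pos_keys)
  if (!any(keep)) return(empty_pairs())
  out <- make_pairs(mp[keep, 1L], mp[keep, 2L], 0L)
  out <- out[order(out$id_a, out$id_b, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter records by sequence length
#'
#' Removes (does not truncate) records longer than `max_len` amino acids.
#'
#' @param records Protein record data.frame.
#' @param max_len Inclusive length cap (default 1024).
#' @return Filtered data.frame.
#' @export
filter_by_length <- function(records, max_len = 1024L) {
  stopifnot(max_len >= 1L)
  out <- records[records$length <= max_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Global-alignment sequence identity
#'
#' Default comparator for the redundancy filter: Needleman-Wunsch global
#' alignment (BLOSUM62, gap opening 10, extension 0.5) with identity
#' defined as matches divided by alignment length, as a fraction in
#' `[0, 1]`.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @return Identity fraction.
#' @export
sequence_identity <- function(seq_a, seq_b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5
  )
  Biostrings::pid(aln, type = "PID1") / 100
}

#' Greedy sequence-redundancy filter
#'
#' Iterates records longest-first and keeps a record only if its identity
#' to every already-kept record does not exceed `identity_threshold`.  The
#' comparator is pluggable; the default is global-alignment identity.
#'
#' @param records Protein record data.frame.
#' @param identity_threshold Fraction in (0, 1] (default 0.5).
#' @param identity_fun Function `(seq_a, seq_b) -> fraction`.
#' @return Filtered data.frame (representatives only).
#' @export
redundancy_filter <- function(records, identity_threshold = 0.5,
                              identity_fun = sequence_identity) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(records) <= 1L) return(records)
  ord <- order(-records$length, records$protein_id, method = "radix")
  records <- records[ord, , drop = FALSE]
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    kept <- which(keep)
    redundant <- FALSE
    for (j in kept) {
      if (identity_fun(records$sequence[i], records$sequence[j]) >
          identity_threshold) {
        redundant <- TRUE
        break
      }
    }
    keep[i] <- !redundant
  }
  out <- records[keep, , drop = FALSE]
  out <- out[order(out$protein_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the self-pair expansion dataset
#'
#' Positives are `(P, P)` self-pairs for every protein appearing in any
#' condensate; negative candidates are proteins that appear in no
#' condensate and have no direct interaction-network edge to any
#' condensate protein (excluding likely false negatives).  Both sets pass
#' the sequence-redundancy filter before pairing.
#'
#' @param condensates A [condensate_table()].
#' @param ppi PPI data.frame from [ppi_network()].
#' @param all_proteins Protein record data.frame covering the candidate
#'   universe.
#' @param identity_threshold Redundancy threshold (default 0.5).
#' @param identity_fun Identity comparator.
#' @return Pair data.frame of self-pairs (`is_self_pair = TRUE`).
#' @export
build_self_pair_dataset <- function(condensates, ppi, all_proteins,
                                    identity_threshold = 0.5,
                                    identity_fun = sequence_identity) {
  stopifnot(inherits(condensates, "codroplet_condensates"))
  cond_prot <- sort(unique(unlist(condensates, use.names = FALSE)))
  excluded <- ppi_neighbours(ppi, cond_prot)
  neg_ids <- setdiff(all_proteins$protein_id, union(cond_prot, excluded))

  pos_rec <- all_proteins[all_proteins$protein_id %in% cond_prot, , drop = FALSE]
  neg_rec <- all_proteins[all_proteins$protein_id %in% neg_ids, , drop = FALSE]
  pos_rec <- redundancy_filter(pos_rec, identity_threshold, identity_fun)
  neg_rec <- redundancy_filter(neg_rec, identity_threshold, identity_fun)

  if (nrow(neg_rec) == 0L) {
    warning("self-pair negative pool is empty after exclusion/filtering")
  }
  rbind(
    if (nrow(pos_rec)) make_pairs(pos_rec$protein_id, pos_rec$protein_id, 1L,
                                  is_self_pair = TRUE) else empty_pairs(),
    if (nrow(neg_rec)) make_pairs(neg_rec$protein_id, neg_rec$protein_id, 0L,
                                  is_self_pair = TRUE) else empty_pairs()
  )
}

#' Condensate-aware train/test split
#'
#' Condensates are shuffled (seeded) and assigned to the training side
#' until the training share of positive pairs reaches `fraction`; the rest
#' go to the test side.  A positive pair enters the test set only if all
#' of its source condensates are test-assigned, and the training set only
#' if all are train-assigned; pairs straddling the two sides are dropped
#' (and reported), preserving the guarantee that no positive test pair
#' shares a condensate with training pairs.  Negatives are split at the
#' same fraction (seeded) with no condensate constraint.
#'
#' @param pairs Pair data.frame (positives must carry `sources`).
#' @param condensates A [condensate_table()].
#' @param fraction Training fraction in (0, 1) (default 0.8).
#' @param seed Integer seed.
#' @return List with elements `train`, `test` (pair data.frames),
#'   `train_condensates`, `dropped` (straddling positive pairs).
#' @export
split_by_condensate <- function(pairs, condensates, fraction = 0.8,
                                seed = 1L) {
  if (!(fraction > 0 && fraction < 1)) {
    stop("fraction must be in (0, 1)", call. = FALSE)
  }
  pos <- pairs[pairs$label == 1L, , drop = FALSE]
  neg <- pairs[pairs$label == 0L, , drop = FALSE]
  if (nrow(pos) && any(!nzchar(pos$sources) & !pos$is_self_pair)) {
    stop("every non-self positive pair must carry source condensates",
         call. = FALSE)
  }

  cids <- names(condensates)
  src_list <- strsplit(pos$sources, ",", fixed = TRUE)
  pair_weight <- table(factor(unlist(src_list), levels = cids))

  ord <- with_seed(derive_seed(seed, "cond-split"), sample(seq_along(cids)))
  cum <- cumsum(as.numeric(pair_weight[ord]))
  total <- sum(pair_weight)
  n_train <- if (total > 0) which(cum >= fraction * total)[1L] else
    max(1L, round(fraction * length(cids)))
  train_c <- cids[ord[seq_len(n_train)]]

  in_train <- vapply(src_list, function(s) all(s %in% train_c), logical(1L))
  in_test <- vapply(src_list, function(s) length(s) > 0L && !any(s %in% train_c),
                    logical(1L))
  # self-pairs have no sources: split them like negatives
  selfpos <- !nzchar(pos$sources)
  straddle <- !selfpos & !in_train & !in_test
  if (any(straddle)) {
    message(sprintf("dropping %d positive pair(s) straddling the split",
                    sum(straddle)))
  }

  split_flat <- function(df, tag) {
    if (!nrow(df)) return(list(train = df, test = df))
    idx <- with_seed(derive_seed(seed, tag), sample(nrow(df)))
    n_tr <- floor(fraction * nrow(df))
    list(train = df[sort(idx[seq_len(n_tr)]), , drop = FALSE],
         test = df[sort(idx[-seq_len(n_tr)]), , drop = FALSE])
  }
  neg_split <- split_flat(neg, "neg-split")
  selfpos_split <- split_flat(pos[selfpos, , drop = FALSE], "selfpos-split")

  train <- rbind(pos[!selfpos & in_train, , drop = FALSE],
                 selfpos_split$train, neg_split$train)
  test <- rbind(pos[!selfpos & in_test, , drop = FALSE],
                selfpos_split$test, neg_split$test)
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test, train_condensates = train_c,
       dropped = pos[straddle, , drop = FALSE])
}

#' Rebalance classes by oversampling
#'
#' Oversamples the minority class with replacement until the class counts
#' are equal, then shuffles the rows (seeded).
#'
#' @param pairs Pair data.frame with both classes present.
#' @param seed Integer seed.
#' @return Resampled pair data.frame with a 1:1 class ratio.
#' @export
rebalance <- function(pairs, seed = 1L) {
  n_pos <- sum(pairs$label == 1L)
  n_neg <- sum(pairs$label == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("rebalance requires both classes to be nonempty", call. = FALSE)
  }
  with_seed(derive_seed(seed, "rebalance"), {
    pos <- which(pairs$label == 1L)
    neg <- which(pairs$label == 0L)
    if (n_pos < n_neg) {
      pos <- c(pos, sample(pos, n_neg - n_pos, replace = TRUE))
    } else if (n_neg < n_pos) {
      neg <- c(neg, sample(neg, n_pos - n_neg, replace = TRUE))
    }
    idx <- sample(c(pos, neg))
    out <- pairs[idx, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Write a pair table to TSV
#' @param pairs Pair data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a pair table from TSV
#' @param path TSV path with columns `id_a`, `id_b`, `label` (optional
#'   `sources`, `is_self_pair`).
#' @return Pair data.frame.
#' @export
read_pairs <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("id_a", "id_b", "label") %in% names(df))) {
    stop(sprintf("'%s' must have columns id_a, id_b, label", path),
         call. = FALSE)
  }
  if (is.null(df$sources)) df$sources <- ""
  df$sources <- as.character(df$sources)
  df$sources[is.na(df$sources)] <- ""
  if (is.null(df$is_self_pair)) df$is_self_pair <- df$id_a == df$id_b
  df$label <- as.integer(df$label)
  df
}
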