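# Per-protein feature bundles: the adapter type for externally computed
# AlphaFold2 representations, a deterministic surrogate generator with a
# planted pairwise-compatibility signal, and a keyed on-disk store.

#' Construct a feature bundle
#'
#' Holds the three per-protein representations consumed by the network: a
#' single-sequence representation (`L x c_msa`), a pair representation
#' (`L x L x c_pair`) and a structure representation (`L x c_struc`).
#'
#' @param protein_id Identifier string.
#' @param f_msa `L x c_msa` numeric matrix.
#' @param f_pair `L x L x c_pair` numeric array.
#' @param f_struc `L x c_struc` numeric matrix.
#' @return Object of class `codroplet_bundle`.
#' @export
feature_bundle <- function(protein_id, f_msa, f_pair, f_struc) {
  stopifnot(is.matrix(f_msa), is.matrix(f_struc), length(dim(f_pair)) == 3L)
  L <- nrow(f_msa)
  if (L < 1L) stop("bundle must contain at least one residue", call. = FALSE)
  if (nrow(f_struc) != L || dim(f_pair)[1L] != L || dim(f_pair)[2L] != L) {
    stop("f_msa, f_pair and f_struc disagree on the residue count", call. = FALSE)
  }
  if (!all(is.finite(f_msa)) || !all(is.finite(f_pair)) ||
      !all(is.finite(f_struc))) {
    stop("feature bundle contains non-finite values", call. = FALSE)
  }
  structure(
    list(protein_id = as.character(protein_id), f_msa = f_msa,
         f_pair = f_pair, f_struc = f_struc, L = L),
    class = "codroplet_bundle"
  )
}

#' @export
print.codroplet_bundle <- function(x, ...) {
  cat(sprintf(
    "<codroplet_bundle> %s: L=%d, f_msa %dx%d, f_pair %dx%dx%d, f_struc %dx%d\n",
    x$protein_id, x$L, nrow(x$f_msa), ncol(x$f_msa),
    dim(x$f_pair)[1L], dim(x$f_pair)[2L], dim(x$f_pair)[3L],
    nrow(x$f_struc), ncol(x$f_struc)
  ))
  invisible(x)
}

#' Latent compatibility profile
#'
#' The surrogate generator plants a low-dimensional compatibility vector
#' per protein; proteins of the same synthetic condensate (cluster) share
#' it, which is what makes co-condensation labels recoverable from the
#' generated features.
#'
#' @param protein_id Identifier.
#' @param compatibility_vector Numeric vector of dimension `d_lat`.
#' @param cluster_id Integer synthetic condensate assignment.
#' @return Object of class `codroplet_profile`.
#' @export
latent_profile <- function(protein_id, compatibility_vector, cluster_id) {
  stopifnot(length(compatibility_vector) >= 1L,
            all(is.finite(compatibility_vector)))
  structure(
    list(protein_id = as.character(protein_id),
         compatibility_vector = as.numeric(compatibility_vector),
         cluster_id = as.integer(cluster_id)),
    class = "codroplet_profile"
  )
}

#' Generate latent profiles for a clustered synthetic proteome
#'
#' Draws one compatibility vector per cluster (unit-scale Gaussian) and
#' assigns it to every member, so that same-cluster pairs are compatible
#' and cross-cluster pairs are not.
#'
#' @param protein_ids Character vector of identifiers.
#' @param cluster_ids Integer vector of the same length.
#' @param d_lat Latent dimension (default 8).
#' @param seed Integer seed.
#' @return Named list of [latent_profile()] objects.
#' @export
latent_profiles <- function(protein_ids, cluster_ids, d_lat = 8L, seed = 1L) {
  stopifnot(length(protein_ids) == length(cluster_ids), d_lat >= 1L)
  clusters <- sort(unique(as.integer(cluster_ids)))
  centers <- with_seed(derive_seed(seed, "cluster-centers"), {
    m <- matrix(stats::rnorm(length(clusters) * d_lat), length(clusters))
    rownames(m) <- as.character(clusters)
    m
  })
  out <- lapply(seq_along(protein_ids), function(i) {
    latent_profile(protein_ids[i],
                   centers[as.character(as.integer(cluster_ids[i])), ],
                   cluster_ids[i])
  })
  names(out) <- protein_ids
  out
}

# Fixed random projection bases shared by every protein generated under the
# same seed; they embed residue identity and the latent compatibility
# vector into the three feature spaces.
surrogate_bases <- function(d_lat, dims, seed) {
  with_seed(derive_seed(seed, "surrogate-bases"), {
    k <- 8L  # per-residue embedding width for the pair channel
    list(
      k = k,
      B_aa_msa = matrix(stats::rnorm(20L * dims$c_msa), 20L),
      B_lat_msa = matrix(stats::rnorm(d_lat * dims$c_msa), d_lat),
      B_aa_struc = matrix(stats::rnorm(20L * dims$c_struc), 20L),
      B_lat_struc = matrix(stats::rnorm(d_lat * dims$c_struc), d_lat),
      E_aa = matrix(stats::rnorm(20L * k, sd = 1 / sqrt(20)), 20L),
      E_lat = matrix(stats::rnorm(d_lat * k, sd = 1 / sqrt(d_lat)), d_lat),
      B_pair = matrix(stats::rnorm(k * k * dims$c_pair, sd = 1 / k), k * k)
    )
  })
}

#' Generate surrogate AlphaFold2-style features for one protein
#'
#' Deterministic stand-in for AlphaFold2-derived representations, built for
#' desk-scale experiments.  One-hot residue identity and the protein's
#' latent compatibility vector are embedded through fixed random projection
#' bases (derived from `seed`, shared across proteins); the pair
#' representation is built from outer products of per-residue embeddings so
#' that genuine pairwise structure exists for the pair-bias attention to
#' exploit.  Gaussian noise of scale `noise_sd` is added on top, seeded per
#' protein, so the output is a deterministic function of
#' `(sequence, profile, seed)`.
#'
#' With `noise_sd = 0` the compatibility vector is exactly linearly
#' decodable from the row means of `f_msa`.
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @param profile A [latent_profile()].
#' @param noise_sd Nonnegative noise scale (default 0.1).
#' @param seed Integer seed; use the same seed for every protein of a
#'   dataset so they share projection bases.
#' @param dims Channel dimensions, from [net_config()] or a list with
#'   `c_msa`, `c_pair`, `c_struc`.
#' @return A [feature_bundle()].
#' @export
generate_surrogate_features <- function(sequence, profile, noise_sd = 0.1,
                                        seed = 1L, dims = net_config()) {
  stopifnot(inherits(profile, "codroplet_profile"), noise_sd >= 0)
  chars <- check_sequence(sequence)
  L <- length(chars)
  d_lat <- length(profile$compatibility_vector)
  bases <- surrogate_bases(d_lat, dims, seed)

  onehot <- matrix(0, L, 20L)
  onehot[cbind(seq_len(L), match(chars, AA_ALPHABET20))] <- 1
  lat <- matrix(profile$compatibility_vector, nrow = 1L)

  f_msa <- onehot %*% bases$B_aa_msa +
    rep(drop(lat %*% bases$B_lat_msa), each = L)
  f_struc <- onehot %*% bases$B_aa_struc +
    rep(drop(lat %*% bases$B_lat_struc), each = L)

  emb <- onehot %*% bases$E_aa + rep(drop(lat %*% bases$E_lat), each = L)
  # outer products of per-residue embeddings, projected to c_pair channels
  k <- bases$k
  outer_flat <- matrix(0, L * L, k * k)   # row i + (j-1)L is vec(emb_i o emb_j)
  for (a in seq_len(k)) {
    outer_flat[, ((a - 1L) * k + 1L):(a * k)] <-
      (rep(emb[, a], times = L)) * emb[rep(seq_len(L), each = L), , drop = FALSE]
  }
  f_pair_flat <- outer_flat %*% bases$B_pair

  if (noise_sd > 0) {
    noise_seed <- derive_seed(seed, "noise", profile$protein_id, sequence)
    with_seed(noise_seed, {
      f_msa <- f_msa + stats::rnorm(length(f_msa), sd = noise_sd)
      f_struc <- f_struc + stats::rnorm(length(f_struc), sd = noise_sd)
      f_pair_flat <- f_pair_flat + stats::rnorm(length(f_pair_flat), sd = noise_sd)
    })
  }

  f_pair <- array(f_pair_flat, dim = c(L, L, dims$c_pair))
  feature_bundle(profile$protein_id, f_msa, f_pair, f_struc)
}

# ---- feature store --------------------------------------------------------

#' Create or open a keyed feature store
#'
#' The store is a directory holding one serialized bundle per protein id
#' (hierarchical per-protein groups, streamed one protein at a time), so a
#' dataset never needs to be resident in memory at once.
#'
#' @param path Directory path.
#' @param create Create the directory if missing.
#' @return Object of class `codroplet_store`.
#' @export
feature_store <- function(path, create = TRUE) {
  if (!dir.exists(path)) {
    if (!create) stop(sprintf("feature store '%s' does not exist", path),
                      call. = FALSE)
    dir.create(path, recursive = TRUE)
  }
  structure(list(path = path), class = "codroplet_store")
}

store_file <- function(store, protein_id) {
  if (grepl("[/\\\\]", protein_id)) {
    stop("protein ids must not contain path separators", call. = FALSE)
  }
  file.path(store$path, paste0(protein_id, ".rds"))
}

#' Save a bundle into a feature store
#' @param store A [feature_store()].
#' @param bundle A [feature_bundle()].
#' @return The store, invisibly.
#' @export
save_features <- function(store, bundle) {
  stopifnot(inherits(store, "codroplet_store"),
            inherits(bundle, "codroplet_bundle"))
  saveRDS(bundle, store_file(store, bundle$protein_id))
  invisible(store)
}

#' Load a bundle from a feature store
#' @param store A [feature_store()] (or its path).
#' @param protein_id Identifier to load.
#' @return The stored [feature_bundle()].
#' @export
load_features <- function(store, protein_id) {
  if (is.character(store)) store <- feature_store(store, create = FALSE)
  f <- store_file(store, protein_id)
  if (!file.exists(f)) {
    stop(sprintf("protein '%s' not found in store '%s' (available: %s)",
                 protein_id, store$path,
                 paste(store_ids(store), collapse = ", ")), call. = FALSE)
  }
  readRDS(f)
}

#' List protein ids available in a store
#' @param store A [feature_store()].
#' @return Character vector of ids.
#' @export
store_ids <- function(store) {
  if (is.character(store)) store <- feature_store(store, create = FALSE)
  sort(sub("\\.rds$", "", list.files(store$path, pattern = "\\.rds$")))
}

# ---- sequences ------------------------------------------------------------

#' Read protein records from a FASTA file
#'
#' @param path FASTA file path.
#' @return data.frame with columns `protein_id`, `sequence`, `length`.
#' @export
read_fasta_records <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(aa), "\\s+"), `[`, character(1L), 1L)
  protein_records(ids, as.character(aa))
}

#' Build a protein record table
#' @param protein_id Character vector of identifiers.
#' @param sequence Character vector of amino-acid sequences.
#' @return data.frame with columns `protein_id`, `sequence`, `length`.
#' @export
protein_records <- function(protein_id, sequence) {
  stopifnot(length(protein_id) == length(sequence), !anyDuplicated(protein_id))
  data.frame(protein_id = unname(as.character(protein_id)),
             sequence = unname(as.character(sequence)),
             length = unname(nchar(sequence)), stringsAsFactors = FALSE)
}

#' Write protein records to FASTA
#' @param records Protein record data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_records <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$protein_id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Generate a random synthetic proteome
#'
#' Uniform random sequences over the 20-letter alphabet, used to exercise
#' the pipeline at desk scale.
#'
#' @param n Number of proteins.
#' @param length_range Integer vector of length 2: min and max length.
#' @param seed Integer seed.
#' @param prefix Identifier prefix.
#' @return Protein record data.frame.
#' @export
synthetic_proteome <- function(n, length_range = c(40L, 200L), seed = 1L,
                               prefix = "P") {
  stopifnot(n >= 1L, length(length_range) == 2L)
  with_seed(derive_seed(seed, "proteome"), {
    lens <- sample(length_range[1L]:length_range[2L], n, replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = "")
    }, character(1L))
    protein_records(sprintf("%s%04d", prefix, seq_len(n)), seqs)
  })
}

#' Featurize a set of proteins into a store
#'
#' Generates surrogate features for every record and saves them under the
#' record's id.  Cluster assignments (synthetic condensate identity) drive
#' the planted compatibility signal.
#'
#' @param records Protein record data.frame.
#' @param store A [feature_store()] or path.
#' @param cluster_ids Integer vector (default: all one cluster).
#' @param noise_sd Noise scale.
#' @param d_lat Latent dimension.
#' @param seed Integer seed.
#' @param dims Channel dimensions (see [generate_surrogate_features()]).
#' @return The store, invisibly.
#' @export
featurize_records <- function(records, store,
                              cluster_ids = rep(1L, nrow(records)),
                              noise_sd = 0.1, d_lat = 8L, seed = 1L,
                              dims = net_config()) {
  if (is.character(store)) store <- feature_store(store)
  profiles <- latent_profiles(records$protein_id, cluster_ids, d_lat, seed)
  for (i in seq_len(nrow(records))) {
    b <- generate_surrogate_features(records$sequence[i],
                                     profiles[[records$protein_id[i]]],
                                     noise_sd, seed, dims)
    save_features(store, b)
  }
  invisible(store)
}
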