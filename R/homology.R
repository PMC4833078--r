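#' @importFrom dplyr arrange group_by summarise mutate filter select slice
#'   ungroup left_join inner_join bind_rows desc n rename distinct
NULL

# Unique k-mers of a sequence (character vector).
seq_kmers <- function(x, k = 4) {
  n <- nchar(x)
  if (n < k) return(character(0))
  unique(substring(x, 1:(n - k + 1), k:n))
}

# Candidate pairs sharing k-mers. A pair (i, j) is kept when its shared
# unique-k-mer count reaches max(min_shared, min_shared_frac * shorter
# sequence length). Returns a two-column integer matrix of row indices
# (i < j). This is the seeding step that keeps the all-vs-all stage at
# desk scale, in the spirit of word-based search heuristics; the
# length-proportional term keeps long random sequences from seeding by
# chance.
candidate_pairs <- function(seqs, k = 4, min_shared = 4,
                            min_shared_frac = 0.02,
                            max_kmer_group = 200) {
  km <- lapply(seqs, seq_kmers, k = k)
  df <- data.frame(kmer = unlist(km),
                   idx = rep(seq_along(seqs), lengths(km)))
  groups <- split(df$idx, df$kmer)
  groups <- groups[lengths(groups) >= 2 & lengths(groups) <= max_kmer_group]
  if (length(groups) == 0) return(matrix(integer(0), 0, 2))
  pair_list <- lapply(groups, function(g) {
    g <- sort(g)
    t(utils::combn(g, 2))
  })
  pairs <- do.call(rbind, pair_list)
  key <- pairs[, 1] * (length(seqs) + 1) + pairs[, 2]
  counts <- table(key)
  ij <- cbind(as.numeric(names(counts)) %/% (length(seqs) + 1),
              as.numeric(names(counts)) %% (length(seqs) + 1))
  lens <- nchar(seqs)
  need <- pmax(min_shared,
               ceiling(min_shared_frac * pmin(lens[ij[, 1]], lens[ij[, 2]])))
  ij[as.numeric(counts) >= need, , drop = FALSE]
}

hit_row_stats <- function(aln) {
  # gap opens: jumps in either coordinate between consecutive aligned pairs
  p <- aln$pairs
  gaps <- 0L
  if (nrow(p) > 1) {
    gaps <- sum(diff(p[, 1]) > 1) + sum(diff(p[, 2]) > 1)
  }
  list(mism = aln$n_aligned - round(aln$identity * aln$n_aligned),
       gap_opens = gaps)
}

#' All-vs-all local-alignment hit table
#'
#' Aligns every candidate pair of proteins (both within and between
#' species) with [smith_waterman()] and reports a BLAST-style hit table.
#' Candidate pairs are seeded by shared-tetramer counts (`min_shared`
#' unique k-mers in common) before dynamic programming; unrelated random
#' pairs almost never pass the seed, which keeps the search tractable while
#' leaving homologous pairs untouched. Both orientations of every surviving
#' pair are reported; self-hits are never reported.
#'
#' @param proteins Protein tibble (`species`, `protein_id`, `sequence`).
#' @param matrix,gap_open,gap_extend Alignment scoring (see
#'   [smith_waterman()]).
#' @param K,lambda Karlin-Altschul constants (see [karlin_evalue()]).
#' @param k,min_shared,min_shared_frac Seeding word size, minimum
#'   shared-word count, and its length-proportional floor (see
#'   `candidate_pairs`).
#' @param min_score Raw-score floor below which pairs are not reported.
#' @return Hit tibble with columns
#'   `query_species, query_id, subject_species, subject_id, identity,
#'   align_length, mismatches, gap_opens, q_start, q_end, s_start, s_end,
#'   evalue, bitscore`.
#' @export
all_vs_all_hits <- function(proteins, matrix = blosum62(), gap_open = 11,
                            gap_extend = 1, K = 0.041, lambda = 0.267,
                            k = 4, min_shared = 4, min_shared_frac = 0.02,
                            min_score = 40) {
  pairs <- candidate_pairs(proteins$sequence, k = k,
                           min_shared = min_shared,
                           min_shared_frac = min_shared_frac)
  rows <- vector("list", nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    aln <- smith_waterman(proteins$sequence[i], proteins$sequence[j],
                          matrix, gap_open, gap_extend)
    if (aln$score < min_score || aln$n_aligned == 0) next
    ka <- karlin_evalue(aln$score, nchar(proteins$sequence[i]),
                        nchar(proteins$sequence[j]), K, lambda)
    st <- hit_row_stats(aln)
    rows[[r]] <- tibble(
      query_species = proteins$species[c(i, j)],
      query_id = proteins$protein_id[c(i, j)],
      subject_species = proteins$species[c(j, i)],
      subject_id = proteins$protein_id[c(j, i)],
      identity = aln$identity, align_length = aln$n_aligned,
      mismatches = st$mism, gap_opens = st$gap_opens,
      q_start = c(aln$a_start, aln$b_start),
      q_end = c(aln$a_end, aln$b_end),
      s_start = c(aln$b_start, aln$a_start),
      s_end = c(aln$b_end, aln$a_end),
      evalue = ka$evalue, bitscore = ka$bitscore)
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(query_species = character(0), query_id = character(0),
                  subject_species = character(0), subject_id = character(0),
                  identity = numeric(0), align_length = integer(0),
                  mismatches = integer(0), gap_opens = integer(0),
                  q_start = integer(0), q_end = integer(0),
                  s_start = integer(0), s_end = integer(0),
                  evalue = numeric(0), bitscore = numeric(0))
  }
  out
}

#' Filter a hit table at the whole-sequence search thresholds
#'
#' Keeps exactly the rows with e-value strictly below 1e-6, identity
#' strictly above 20%, and bit score strictly above 80.
#'
#' @param hits Hit tibble.
#' @return Filtered hit tibble.
#' @export
filter_hits_blast <- function(hits) {
  dplyr::filter(hits, .data$evalue < 1e-6, .data$identity > 0.20,
                .data$bitscore > 80)
}

#' Filter a profile-search hit table
#'
#' Keeps rows with e-value strictly below the significance threshold
#' (default 1e-5, the profile-search cutoff).
#'
#' @param hits Hit tibble with an `evalue` column.
#' @param threshold Strict upper bound on e-value.
#' @return Filtered hit tibble.
#' @export
filter_hits_profile <- function(hits, threshold = 1e-5) {
  dplyr::filter(hits, .data$evalue < threshold)
}

# Top hit of each query within each subject species: max bitscore, ties
# broken by lower evalue then lexicographic subject id.
top_hits_by_species <- function(hits) {
  hits %>%
    arrange(.data$query_species, .data$query_id, .data$subject_species,
            desc(.data$bitscore), .data$evalue, .data$subject_id) %>%
    group_by(.data$query_species, .data$query_id, .data$subject_species) %>%
    slice(1) %>%
    ungroup()
}

#' Best reciprocal hits against the reference species
#'
#' Reports pairs `(r, x)` where `r` (a reference-species protein) is `x`'s
#' top hit in the reference species and `x` is `r`'s top hit within `x`'s
#' species. "Top" means highest bit score, ties broken by lower e-value and
#' then lexicographic id. The input must be a filtered hit table containing
#' both search directions.
#'
#' @param hits Filtered hit tibble.
#' @param reference_species Species label playing the reference role.
#' @return Tibble with columns `reference_id`, `species`, `protein_id`,
#'   `bitscore` (of the forward hit).
#' @export
best_reciprocal_hits <- function(hits, reference_species) {
  tops <- top_hits_by_species(hits)
  fwd <- tops %>%  # x (non-reference) -> its best hit r in the reference
    filter(.data$subject_species == reference_species,
           .data$query_species != reference_species) %>%
    select(species = "query_species", protein_id = "query_id",
           reference_id = "subject_id", bitscore = "bitscore")
  rev <- tops %>%  # r -> its best hit within each other species
    filter(.data$query_species == reference_species,
           .data$subject_species != reference_species) %>%
    select(reference_id = "query_id", species = "subject_species",
           back_id = "subject_id")
  fwd %>%
    inner_join(rev, by = c("reference_id", "species")) %>%
    filter(.data$protein_id == .data$back_id) %>%
    select("reference_id", "species", "protein_id", "bitscore") %>%
    arrange(.data$reference_id, .data$species, .data$protein_id)
}

#' Cluster proteins into orthogroups
#'
#' Orthogroups are the connected components of the undirected graph whose
#' edges are reciprocal filtered hits (both search directions present in
#' the filtered table). Every input protein lands in exactly one group;
#' proteins with no edges become singletons. A group acquires a family
#' label when it contains a reference query protein carrying one;
#' conflicting labels within one group flag it `ambiguous` (label `NA`)
#' rather than being silently resolved.
#'
#' @param hits Filtered hit tibble.
#' @param proteins Protein tibble defining the clustering universe.
#' @param queries Optional tibble of labelled reference queries
#'   (`species`, `protein_id`, `family`).
#' @return Tibble with columns `group_id`, `species`, `protein_id`,
#'   `family`, `ambiguous`, `contains_reference_query`.
#' @export
cluster_orthogroups <- function(hits, proteins, queries = NULL) {
  key <- function(sp, id) paste0(sp, "|", id)
  verts <- key(proteins$species, proteins$protein_id)
  if (anyDuplicated(verts)) abort("duplicate (species, protein_id) pairs")
  g <- igraph::make_empty_graph(n = length(verts), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = verts)
  if (nrow(hits)) {
    a <- key(hits$query_species, hits$query_id)
    b <- key(hits$subject_species, hits$subject_id)
    fwd <- paste0(a, "->", b)
    rev <- paste0(b, "->", a)
    recip <- fwd %in% rev
    if (any(recip)) {
      ab <- cbind(a, b)[recip, , drop = FALSE]
      ekeep <- unique(cbind(pmin(ab[, 1], ab[, 2]), pmax(ab[, 1], ab[, 2])))
      ekeep <- ekeep[ekeep[, 1] %in% verts & ekeep[, 2] %in% verts &
                       ekeep[, 1] != ekeep[, 2], , drop = FALSE]
      if (nrow(ekeep)) {
        g <- igraph::add_edges(g, t(matrix(match(ekeep, verts), ncol = 2)))
      }
    }
  }
  comp <- igraph::components(g)$membership
  out <- tibble(species = proteins$species,
                protein_id = proteins$protein_id,
                component = comp[match(verts, names(comp))])
  # stable group ids: number components by their first member in input order
  first <- !duplicated(out$component)
  relab <- stats::setNames(seq_len(sum(first)), out$component[first])
  out$group_id <- sprintf("OG%04d", relab[as.character(out$component)])
  out$component <- NULL
  if (!is.null(queries) && nrow(queries)) {
    qkey <- key(queries$species, queries$protein_id)
    qfam <- stats::setNames(queries$family, qkey)
    out$query_family <- unname(qfam[key(out$species, out$protein_id)])
  } else {
    out$query_family <- NA_character_
  }
  lab <- out %>%
    group_by(.data$group_id) %>%
    summarise(
      contains_reference_query = any(!is.na(.data$query_family)),
      n_fam = dplyr::n_distinct(.data$query_family, na.rm = TRUE),
      family = if (dplyr::n_distinct(.data$query_family, na.rm = TRUE) == 1)
        unique(stats::na.omit(.data$query_family)) else NA_character_,
      .groups = "drop") %>%
    mutate(ambiguous = .data$n_fam > 1) %>%
    select("group_id", "family", "ambiguous", "contains_reference_query")
  out %>%
    select(-"query_family") %>%
    left_join(lab, by = "group_id") %>%
    select("group_id", "species", "protein_id", "family", "ambiguous",
           "contains_reference_query") %>%
    arrange(.data$group_id, .data$species, .data$protein_id)
}

#' Global percent identity of two sequences
#'
#' Needleman-Wunsch global alignment (affine gaps, same scoring defaults as
#' [smith_waterman()]); identity is the fraction of alignment columns
#' (including gap columns) where both sequences hold the same residue.
#'
#' @param seq_a,seq_b Amino-acid strings.
#' @param matrix,gap_open,gap_extend Scoring parameters.
#' @return Identity fraction in `[0, 1]`.
#' @export
global_identity <- function(seq_a, seq_b, matrix = blosum62(),
                            gap_open = 11, gap_extend = 1) {
  S <- matrix[AA_ALPHABET, AA_ALPHABET]
  ops <- profile_align_cpp(msa_profile(seq_a), msa_profile(seq_b),
                           S, gap_open, gap_extend)
  rows <- merge_by_ops(seq_a, seq_b, ops)
  a <- strsplit(rows[1], "")[[1]]; b <- strsplit(rows[2], "")[[1]]
  sum(a == b & a != "-") / length(a)
}

#' Collapse suspected haplotype duplicates within a species
#'
#' Within-species pairs whose global identity meets the threshold are taken
#' to be the same locus annotated twice (e.g. haplotypes assembled as
#' separate contigs); each identity-connected group is collapsed to its
#' longest member (ties broken by lexicographically smallest id).
#'
#' @param proteins Protein tibble for one species.
#' @param identity_threshold Minimum global identity for a merge
#'   (default 0.99).
#' @return A list with `proteins` (survivors, input order preserved) and
#'   `report` (tibble: `species`, `kept_id`, `removed_id`, `identity`).
#' @export
collapse_haplotypes <- function(proteins, identity_threshold = 0.99) {
  if (length(unique(proteins$species)) > 1) {
    abort("collapse_haplotypes expects records from one species")
  }
  n <- nrow(proteins)
  report <- tibble(species = character(0), kept_id = character(0),
                   removed_id = character(0), identity = numeric(0))
  if (n < 2) return(list(proteins = proteins, report = report))
  # near-duplicates share the bulk of their k-mers; demand half
  pairs <- candidate_pairs(proteins$sequence, k = 4, min_shared = 4,
                           min_shared_frac = 0.5)
  if (nrow(pairs) == 0) return(list(proteins = proteins, report = report))
  keep_edge <- logical(nrow(pairs)); ident <- numeric(nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    ident[r] <- global_identity(proteins$sequence[pairs[r, 1]],
                                proteins$sequence[pairs[r, 2]])
    keep_edge[r] <- ident[r] >= identity_threshold
  }
  pairs <- pairs[keep_edge, , drop = FALSE]
  ident <- ident[keep_edge]
  if (nrow(pairs) == 0) return(list(proteins = proteins, report = report))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(pairs))
  comp <- igraph::components(g)$membership
  removed <- integer(0)
  rep_rows <- list()
  for (cc in unique(comp[tabulate(comp) > 1])) {
    members <- which(comp == cc)
    lens <- nchar(proteins$sequence[members])
    ord <- order(-lens, proteins$protein_id[members])
    keeper <- members[ord[1]]
    for (m in members[ord[-1]]) {
      removed <- c(removed, m)
      edge_id <- which((pairs[, 1] == keeper & pairs[, 2] == m) |
                       (pairs[, 2] == keeper & pairs[, 1] == m))
      idval <- if (length(edge_id)) max(ident[edge_id]) else
        global_identity(proteins$sequence[keeper], proteins$sequence[m])
      rep_rows[[length(rep_rows) + 1]] <- tibble(
        species = proteins$species[m],
        kept_id = proteins$protein_id[keeper],
        removed_id = proteins$protein_id[m],
        identity = idval)
    }
  }
  list(proteins = proteins[setdiff(seq_len(n), removed), ],
       report = bind_rows(report, bind_rows(rep_rows)) %>%
         arrange(.data$kept_id, .data$removed_id))
}
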