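#' Labelled multiple sequence alignment
#'
#' Bundle an aligned set of nucleotide sequences with per-sample metadata
#' (individual, species, population, marker, allele copy). This is the hub
#' object consumed by the mismatch, AMOVA, network and divergence stages.
#'
#' @param seqs Character vector of equal-length sequences over
#'   `A,C,G,T,-,N` (IUPAC ambiguity codes other than `N` are recoded to `N`;
#'   `U` is mapped to `T`; case is ignored). Names, if present, must match
#'   `meta$sample_id`.
#' @param meta Data frame with columns `sample_id`, `individual_id`,
#'   `species`, `population`, `marker`, `allele_copy`, one row per sequence,
#'   aligned index-for-index with `seqs`.
#' @return An object of class `labeled_alignment`: a list with elements
#'   `seq` (named character vector), `meta` (data frame) and `length`
#'   (alignment length in bp). Alignment columns are 0-based internally and
#'   1-based in reports.
#' @export
labeled_alignment <- function(seqs, meta) {
  seqs <- toupper(as.character(seqs))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ## anything that is not A/C/G/T/- becomes N (phased data carry no
  ## ambiguity codes; unphased leftovers are treated as missing)
  seqs <- gsub("[^ACGT-]", "N", seqs)
  if (length(seqs) == 0L) stop("alignment error: no sequences")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("alignment error: sequences have unequal lengths (",
         paste(sort(unique(lens)), collapse = ", "), ")")
  if (lens[1] == 0L) stop("alignment error: zero-length sequences")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  required <- c("sample_id", "individual_id", "species", "population",
                "marker", "allele_copy")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  if (nrow(meta) != length(seqs))
    stop("join error: ", length(seqs), " sequences but ",
         nrow(meta), " metadata rows")
  if (!is.null(names(seqs)) && !identical(names(seqs), meta$sample_id)) {
    idx <- match(names(seqs), meta$sample_id)
    if (anyNA(idx))
      stop("join error: unmatched metadata ids: ",
           paste(utils::head(names(seqs)[is.na(idx)], 5), collapse = ", "))
    meta <- meta[idx, , drop = FALSE]
  }
  names(seqs) <- meta$sample_id
  key <- paste(meta$individual_id, meta$marker, meta$allele_copy)
  if (anyDuplicated(key))
    stop("metadata error: duplicated (individual, marker, allele_copy): ",
         key[duplicated(key)][1])
  if (any(!nzchar(meta$species)) || any(!nzchar(meta$population)))
    stop("metadata error: empty species or population labels")
  rownames(meta) <- NULL
  structure(list(seq = seqs, meta = meta, length = lens[1]),
            class = "labeled_alignment")
}

#' @export
print.labeled_alignment <- function(x, ...) {
  cat("labeled_alignment:", length(x$seq), "sequences x", x$length, "bp\n")
  cat("  species:",
      paste(names(table(x$meta$species)), table(x$meta$species),
            sep = "=", collapse = ", "), "\n")
  cat("  populations:", length(unique(x$meta$population)),
      " markers:", paste(unique(x$meta$marker), collapse = ","), "\n")
  invisible(x)
}

#' Read a labelled alignment from FASTA plus a TSV metadata table
#'
#' FASTA record ids and metadata `sample_id`s must join one to one.
#'
#' @param fasta_path Path to an (aligned) FASTA file.
#' @param metadata_path Path to a tab-separated metadata table with header
#'   `sample_id individual_id species population marker allele_copy`.
#' @return A [labeled_alignment()].
#' @export
read_alignment <- function(fasta_path, metadata_path) {
  dna <- ape::read.FASTA(fasta_path)
  seqs <- vapply(as.character(dna), function(ch) paste(ch, collapse = ""), "")
  names(seqs) <- names(dna)
  meta <- utils::read.delim(metadata_path, stringsAsFactors = FALSE,
                            colClasses = "character")
  if (anyNA(match(names(seqs), meta$sample_id)) ||
      anyNA(match(meta$sample_id, names(seqs))))
    stop("join error: FASTA ids and metadata sample_ids do not match 1:1")
  labeled_alignment(seqs, meta[match(names(seqs), meta$sample_id), ])
}

#' Write a labelled alignment as FASTA plus a TSV metadata table
#'
#' @param aln A [labeled_alignment()].
#' @param fasta_path,metadata_path Output paths.
#' @return Invisibly, `aln`.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path) {
  con <- file(fasta_path, "w")
  on.exit(close(con))
  writeLines(paste0(">", names(aln$seq), "\n", unname(aln$seq)), con)
  utils::write.table(aln$meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(aln)
}

#' Duplicate haploid sequences into the two-allele-copy convention
#'
#' Nuclear markers enter the analyses as two phased allele copies per
#' individual (`a` and `b`). A haploid (mitochondrial) marker is replicated
#' twice per individual so that every individual carries the same number of
#' gene copies at every marker.
#'
#' @param aln A [labeled_alignment()] with one copy per individual.
#' @return A [labeled_alignment()] with each sequence present twice,
#'   `allele_copy` set to `a`/`b` and `sample_id` suffixed accordingly.
#' @export
duplicate_haploid_copies <- function(aln) {
  if (anyDuplicated(aln$meta$individual_id))
    stop("input must contain one copy per individual")
  idx <- rep(seq_along(aln$seq), each = 2)
  meta <- aln$meta[idx, , drop = FALSE]
  meta$allele_copy <- rep(c("a", "b"), length(aln$seq))
  meta$sample_id <- paste0(meta$individual_id, "_", meta$allele_copy)
  seqs <- aln$seq[idx]
  names(seqs) <- meta$sample_id
  labeled_alignment(seqs, meta)
}

## sequences -> integer matrix (rows = samples); 0 codes missing (- or N)
.aln_matrix <- function(aln) {
  ch <- strsplit(aln$seq, "", fixed = TRUE)
  m <- matrix(0L, length(ch), aln$length,
              dimnames = list(names(aln$seq), NULL))
  code <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (i in seq_along(ch)) {
    v <- code[ch[[i]]]
    v[is.na(v)] <- 0L
    m[i, ] <- v
  }
  m
}

#' Pairwise difference matrix
#'
#' Count the number of differing sites between every pair of sequences,
#' under one of two missing-data policies: `complete_deletion` drops every
#' column containing a gap or `N` for all pairs (one shared site set),
#' `pairwise_deletion` drops such columns per pair.
#'
#' @param aln A [labeled_alignment()].
#' @param missing_policy `"complete_deletion"` (default; keeps all distances
#'   on one site scale, used by the mismatch and network stages) or
#'   `"pairwise_deletion"`.
#' @return An integer matrix of class `pdiff_matrix` with attributes
#'   `sites_used` (columns retained: a scalar under complete deletion, the
#'   per-pair matrix under pairwise deletion) and `missing_policy`.
#' @export
pairwise_differences <- function(aln,
                                 missing_policy = c("complete_deletion",
                                                    "pairwise_deletion")) {
  missing_policy <- match.arg(missing_policy)
  m <- .aln_matrix(aln)
  if (missing_policy == "complete_deletion") {
    keep <- colSums(m == 0L) == 0L
    if (!any(keep))
      stop("degenerate input: zero sites retained after complete deletion")
    m <- m[, keep, drop = FALSE]
    sites <- ncol(m)
  }
  ## one-hot cross products: d_ij = (# sites both defined) - (# agreements)
  valid <- (m != 0L) * 1
  npair_sites <- tcrossprod(valid)
  agree <- matrix(0, nrow(m), nrow(m))
  for (b in 1:4) agree <- agree + tcrossprod((m == b) * 1)
  d <- round(npair_sites - agree)
  storage.mode(d) <- "integer"
  dimnames(d) <- list(rownames(m), rownames(m))
  diag(d) <- 0L
  if (missing_policy == "pairwise_deletion") {
    storage.mode(npair_sites) <- "integer"
    if (all(npair_sites[upper.tri(npair_sites)] == 0L))
      stop("degenerate input: zero sites retained for every pair")
    sites <- npair_sites
  }
  structure(d, sites_used = sites, missing_policy = missing_policy,
            class = c("pdiff_matrix", "matrix", "array"))
}

#' Collapse an alignment into its unique haplotypes
#'
#' @param aln A [labeled_alignment()] without missing data among compared
#'   sites (apply complete deletion upstream if needed).
#' @return An object of class `haplotype_table`: list with `haplotypes`
#'   (unique sequences, ordered by first occurrence), `counts` (totals),
#'   `composition` (haplotype x species:population count table) and
#'   `assignment` (haplotype index per input sequence).
#' @export
collapse_haplotypes <- function(aln) {
  idx <- match(aln$seq, unique(aln$seq))
  haps <- unique(aln$seq)
  names(haps) <- paste0("H", seq_along(haps))
  cell <- paste(aln$meta$species, aln$meta$population, sep = ":")
  comp <- table(factor(idx, levels = seq_along(haps)), cell)
  rownames(comp) <- names(haps)
  structure(list(haplotypes = haps,
                 counts = as.integer(tabulate(idx, length(haps))),
                 composition = comp,
                 assignment = stats::setNames(idx, names(aln$seq))),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("haplotype_table:", length(x$haplotypes), "haplotypes from",
      sum(x$counts), "sequences\n")
  invisible(x)
}

## evaluate code with a private RNG stream; global .Random.seed untouched
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(seed)
  force(code)
}

#' Downsample groups to a balanced design
#'
#' Randomly removes whole individuals (both allele copies together) from
#' over-represented groups until every group holds the minimum group size,
#' mirroring the balanced subsampling used before computing the
#' genealogical sorting index on unequal species samples.
#'
#' @param aln A [labeled_alignment()].
#' @param group_field Metadata column defining the groups (default
#'   `"species"`).
#' @param seed Integer seed; the subsample is deterministic given the seed.
#' @return A [labeled_alignment()] in which every group has the same number
#'   of individuals. Already-balanced input is returned with the same
#'   individuals.
#' @export
balance_groups <- function(aln, group_field = "species", seed = NULL) {
  grp <- aln$meta[[group_field]]
  if (is.null(grp)) stop("unknown metadata field: ", group_field)
  ind_grp <- unique(aln$meta[, c("individual_id", group_field)])
  if (length(unique(ind_grp[[group_field]])) < 2L)
    stop("need at least 2 groups to balance")
  sizes <- table(ind_grp[[group_field]])
  k <- min(sizes)
  keep <- with_seed(seed, {
    unlist(lapply(split(ind_grp$individual_id, ind_grp[[group_field]]),
                  function(ids) if (length(ids) == k) ids
                  else sample(ids, k)))
  })
  rows <- aln$meta$individual_id %in% keep
  labeled_alignment(aln$seq[rows], aln$meta[rows, , drop = FALSE])
}

#' Restrict a labelled alignment to a subset of samples
#'
#' @param aln A [labeled_alignment()].
#' @param sample_ids Sample ids to keep (order preserved from `aln`).
#' @return A [labeled_alignment()].
#' @export
subset_alignment <- function(aln, sample_ids) {
  rows <- aln$meta$sample_id %in% sample_ids
  if (!any(rows)) stop("no matching samples")
  labeled_alignment(aln$seq[rows], aln$meta[rows, , drop = FALSE])
}
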