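# Array-design fingerprinting: the dN distance between the SNP position
# sets of two files, corpus clustering into array designs, cluster
# profiles, and assignment of new genomes to a cluster.

#' Number of positions two genotype files do not share
#'
#' The array fingerprint distance: the size of the symmetric difference
#' between two position sets. Zero iff the sets are equal; symmetric;
#' satisfies the triangle inequality.
#'
#' @param a,b position sets from [position_set()] (sorted unique
#'   encoded keys)
#' @return integer-valued count
#' @export
delta_n <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  .symdiff_count(as.numeric(a), as.numeric(b))
}

#' Pairwise fingerprint distance matrix for a corpus
#'
#' @param corpus list of position sets (or of `dtc_genome` objects)
#' @return symmetric numeric matrix with zero diagonal, row/column
#'   names from the corpus names
#' @export
distance_matrix <- function(corpus) {
  stopifnot(length(corpus) >= 2)
  sets <- lapply(corpus, function(x) {
    if (is_genome(x)) position_set(x) else as.numeric(x)
  })
  m <- .symdiff_matrix(sets)
  dimnames(m) <- list(names(corpus), names(corpus))
  m
}

#' Cluster a corpus of genotype files into array designs
#'
#' Single-linkage agglomeration cut at `cutoff`: two files share a
#' cluster iff they are connected by a chain of pairwise distances at or
#' below the cutoff. The 200K default matches real consumer files of
#' 0.5-1M positions; scale it down for smaller synthetic arrays.
#'
#' @param m distance matrix from [distance_matrix()]
#' @param cutoff maximum within-cluster chain distance (default 200000)
#' @return integer vector of cluster labels (1-based, ordered by first
#'   appearance), named like the matrix rows
#' @export
cluster_corpus <- function(m, cutoff = 200000) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), nrow(m) >= 2)
  hc <- stats::hclust(stats::as.dist(m), method = "single")
  raw <- stats::cutree(hc, h = cutoff)
  # relabel in order of first appearance for determinism
  labels <- match(raw, unique(raw))
  names(labels) <- rownames(m)
  labels
}

#' Profile one cluster into an array-design model
#'
#' Computes, for every position seen in any member, the fraction of
#' members reporting it (its prevalence). The reference position set
#' keeps positions above a prevalence floor (dropping file-private
#' junk); the core set is the positions present in every member.
#'
#' @param members list of position sets belonging to one cluster
#' @param cluster_id identifier stored in the model
#' @param floor reference-set prevalence floor (default 0.05)
#' @return object of class `dtc_cluster_model`: list with `cluster_id`,
#'   `n_members`, `positions` (data.table key_/prevalence, floored),
#'   `core` (keys at prevalence 1), `floor`
#' @export
profile_cluster <- function(members, cluster_id = "c1", floor = 0.05) {
  stopifnot(length(members) >= 1)
  keys <- unlist(members, use.names = FALSE)
  tab <- data.table::data.table(key_ = keys)[, .(count = .N), by = key_]
  tab[, prevalence := count / length(members)]
  data.table::setkey(tab, key_)
  kept <- tab[prevalence >= floor]
  structure(
    list(cluster_id = cluster_id,
         n_members = length(members),
         positions = kept[, .(key_, prevalence)],
         core = kept[prevalence == 1, key_],
         floor = floor),
    class = "dtc_cluster_model"
  )
}

#' @export
print.dtc_cluster_model <- function(x, ...) {
  cat(sprintf(
    "<dtc_cluster_model %s: %d members, %d reference positions (%d core)>\n",
    x$cluster_id, x$n_members, nrow(x$positions), length(x$core)))
  invisible(x)
}

#' Coverage of a genome's positions by a cluster model
#'
#' @param model a `dtc_cluster_model`
#' @param g position set (or `dtc_genome`)
#' @return fraction of the genome's positions present in the model's
#'   reference set
#' @export
cluster_coverage <- function(model, g) {
  ps <- if (is_genome(g)) position_set(g) else as.numeric(g)
  if (length(ps) == 0) return(0)
  common <- length(ps) + nrow(model$positions) -
    .symdiff_count(ps, model$positions$key_)
  (common / 2) / length(ps)
}

#' Assign a genome to the best-covering array cluster
#'
#' Among the models whose reference positions cover at least
#' `min_coverage` of the genome's positions, the one with maximal
#' coverage wins (ties break to the earliest model in `models`). A
#' genome covered by no model is `"unassigned"`.
#'
#' @param g position set (or `dtc_genome`)
#' @param models list of `dtc_cluster_model`
#' @param min_coverage assignment threshold, inclusive (default 0.8)
#' @return list with `cluster_id` (or `"unassigned"`) and `coverage`
#'   (named vector over all models)
#' @export
assign_cluster <- function(g, models, min_coverage = 0.8) {
  stopifnot(length(models) >= 1)
  cov <- vapply(models, cluster_coverage, numeric(1), g = g)
  ids <- vapply(models, function(m) m$cluster_id, character(1))
  names(cov) <- ids
  eligible <- which(cov >= min_coverage)
  if (length(eligible) == 0) {
    return(list(cluster_id = "unassigned", coverage = cov))
  }
  best <- eligible[which.max(cov[eligible])]
  list(cluster_id = ids[best], coverage = cov)
}

#' Serialize / load a cluster model as TSV with a parameter header
#'
#' @param model a `dtc_cluster_model`
#' @param path file path
#' @return `path` invisibly (`write_cluster_model`); a
#'   `dtc_cluster_model` (`read_cluster_model`)
#' @export
write_cluster_model <- function(model, path) {
  hdr <- sprintf("# dtcqc cluster_model id=%s members=%d floor=%g",
                 model$cluster_id, model$n_members, model$floor)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, "chrom\tpos\tprevalence"), con, sep = "\n")
  dp <- decode_pos(model$positions$key_)
  writeLines(paste(dp$chrom, dp$pos, model$positions$prevalence, sep = "\t"),
             con, sep = "\n")
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  params <- as.list(stats::setNames(sub("^[a-z_]+=", "", kv),
                                    sub("=.*$", "", kv)))
  tab <- data.table::fread(path, skip = 1, sep = "\t",
                           colClasses = list(character = "chrom"))
  tab[, key_ := encode_pos(chrom, pos)]
  data.table::setkey(tab, key_)
  structure(
    list(cluster_id = params$id,
         n_members = as.integer(params$members),
         positions = tab[, .(key_, prevalence)],
         core = tab[prevalence == 1, key_],
         floor = as.numeric(params$floor)),
    class = "dtc_cluster_model"
  )
}
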