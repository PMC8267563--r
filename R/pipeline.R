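# Pipeline drivers: configuration, the single-file QC chain, and corpus
# mode (clustering, blacklists, identity).

#' Pipeline configuration
#'
#' Every threshold used by the stages, overridable individually or from
#' a YAML file. The full effective configuration is embedded in every
#' QC report for provenance.
#'
#' @param ... named overrides of the defaults
#' @param file optional YAML file of overrides (applied before `...`)
#' @return named list of parameters
#' @export
qc_config <- function(..., file = NULL) {
  cfg <- list(
    min_records = 50000,         # plausible genotyping file floor
    max_records = 5e6,           # and ceiling
    max_ref_mismatch = 0.10,     # reference-mismatch fraction ceiling
    strand_flip_hi = 0.8,        # flip score above which repair is tried
    strand_flip_lo = 0.2,        # flip score at or below which a file is clean
    strand_min_informative = 10, # informative probes needed for a verdict
    vcf_min_rows = 1000,         # rows needed for NGS/array triage
    cluster_cutoff = 200000,     # max within-cluster chain distance
    cluster_floor = 0.05,        # cluster-model prevalence floor
    assign_min_coverage = 0.8,   # cluster assignment threshold (inclusive)
    z_crit = 4,                  # blacklist z threshold, both panels
    z_n_min = 30,                # called genomes needed per testable site
    offpanel_max = 0.1,          # off-panel call fraction ceiling
    blacklist_min_cohort = 100,  # cohort size below which to warn
    identity_min_shared = 10000, # shared called sites for a verdict
    dup_cut = 0.975,             # duplicate concordance cutoff (exclusive)
    rel_cut = 0.80               # close-relative cutoff (inclusive)
  )
  if (!is.null(file)) {
    over <- yaml::read_yaml(file)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  if (length(dots) > 0) {
    unknown <- setdiff(names(dots), names(cfg))
    if (length(unknown) > 0) {
      stop("unknown config keys: ", paste(unknown, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  cfg
}

#' Run the single-file QC pipeline
#'
#' Executes, in order: container extraction, format triage, parsing,
#' build detection, reference comparison, the plausibility gate, strand
#' check (array data), VCF triage (VCF data), basic per-SNP filtering,
#' cluster assignment, and blacklist application. Processing stops at
#' the first fatal rejection; a report is always produced.
#'
#' @param path input file (possibly a zip/gzip/bzip2 container)
#' @param cfg configuration from [qc_config()]
#' @param ref optional reference lookup ([read_reference_lookup()])
#' @param sigs build-signature table
#' @param probes strand-probe table
#' @param models optional list of `dtc_cluster_model` for assignment
#' @param blacklists optional named list of `dtc_blacklist` keyed by
#'   cluster id
#' @return list with `report` (a `dtc_qc_report`) and `genome` (the
#'   processed `dtc_genome`, or `NULL` when rejected)
#' @export
run_single <- function(path, cfg = qc_config(), ref = NULL,
                       sigs = read_build_signatures(),
                       probes = read_strand_probes(),
                       models = NULL, blacklists = NULL) {
  stages <- list()
  note <- function(name, status, detail = NULL, counts = NULL) {
    stages[[name]] <<- list(status = status, detail = detail,
                            counts = as.list(counts))
  }
  finish <- function(g, rej = NULL) {
    report <- structure(list(
      file = path,
      source = if (!is.null(g)) g$source else NA_character_,
      build = if (!is.null(g)) g$build else NA_character_,
      data_kind = if (!is.null(g)) g$data_kind else NA_character_,
      cluster = attr(g, "cluster") %||% NA_character_,
      qc_flags = if (!is.null(g)) as.list(g$qc_flags) else list(),
      stages = stages,
      passed = is.null(rej),
      rejection_reason = if (!is.null(rej)) rej$reason else NA_character_,
      rejection_stage = if (!is.null(rej)) rej$stage else NA_character_,
      params = cfg
    ), class = "dtc_qc_report")
    list(report = report, genome = if (is.null(rej)) g else NULL)
  }

  flat <- capture_rejection(extract_container(path), "extract")
  if (is_rejection(flat)) {
    note("extract", "fail", flat$reason)
    return(finish(NULL, flat))
  }
  note("extract", "pass", attr(flat, "container_kind"))

  fmt <- triage_file(flat)
  if (identical(as.character(fmt), "rejected")) {
    rej <- rejection(attr(fmt, "reason"), stage = "triage")
    note("triage", "fail", rej$reason)
    return(finish(NULL, rej))
  }
  note("triage", "pass", as.character(fmt))

  g <- capture_rejection(
    if (fmt == "vcf") parse_vcf_file(flat) else parse_genotype_file(flat, fmt),
    "parse"
  )
  if (is_rejection(g)) {
    note("parse", "fail", g$reason)
    return(finish(NULL, g))
  }
  note("parse", "pass",
       counts = c(n_input_lines = g$n_input_lines, n_parsed = g$n_parsed,
                  n_nocall = g$n_nocall,
                  n_rejected_records = g$n_rejected_records))

  g$build <- detect_build(g, sigs)
  note("build", "pass", g$build)

  if (!is.null(ref)) {
    rc <- compare_to_reference(g, ref)
    note("reference", "pass",
         counts = c(n_compared = rc$n_compared,
                    frac_homref = rc$frac_homref,
                    frac_ref_mismatch = rc$frac_ref_mismatch))
    gate <- sanity_gate(g, rc, cfg)
    if (is_rejection(gate)) {
      note("sanity_gate", "fail", gate$reason)
      return(finish(g, gate))
    }
    note("sanity_gate", "pass")
  } else {
    # no reference supplied: only the record-count bounds can be checked
    gate <- sanity_gate(g, list(frac_ref_mismatch = NA_real_), cfg)
    if (is_rejection(gate)) {
      note("sanity_gate", "fail", gate$reason)
      return(finish(g, gate))
    }
    note("sanity_gate", "pass", "no reference lookup")
  }

  if (fmt == "vcf") {
    g <- triage_vcf_genome(g, min_rows = cfg$vcf_min_rows)
    note("vcf_triage", "pass", g$data_kind)
  } else {
    g$data_kind <- "genotyping"
  }

  if (g$data_kind != "ngs") {
    res <- verify_or_reject(g, probes, cfg)
    if (is_rejection(res)) {
      note("strand", "fail", res$reason)
      return(finish(g, res))
    }
    g <- res
    note("strand", "pass",
         if ("strand_fixed" %in% g$qc_flags) "strand_fixed"
         else if ("strand_unchecked" %in% g$qc_flags) "strand_unchecked"
         else "clean")
  }

  bc <- basic_snp_check(g)
  g <- bc$genome
  note("basic_snp_check", "pass", counts = bc$counts)

  if (!is.null(models)) {
    asg <- assign_cluster(position_set(g), models,
                          min_coverage = cfg$assign_min_coverage)
    attr(g, "cluster") <- asg$cluster_id
    if (asg$cluster_id == "unassigned") {
      g <- add_qc_flag(g, "no_cluster_match")
      note("cluster_assign", "pass", "unassigned")
    } else {
      note("cluster_assign", "pass", asg$cluster_id)
      bl <- blacklists[[asg$cluster_id]]
      if (!is.null(bl)) {
        ab <- apply_blacklist(g, bl, cluster_id = asg$cluster_id)
        g <- ab$genome
        attr(g, "cluster") <- asg$cluster_id
        note("blacklist", "pass", counts = c(n_removed = ab$n_removed))
      }
    }
  }

  finish(g)
}

#' Run corpus-level processing
#'
#' Clusters a corpus of parsed genomes into array designs, profiles
#' each cluster, optionally builds per-cluster blacklists against a
#' supplied allele-frequency table, and runs all pairwise identity
#' comparisons.
#'
#' @param genomes named list of `dtc_genome` (at least 2)
#' @param cfg configuration from [qc_config()]
#' @param freqs optional allele-frequency table for blacklist building
#' @param cutoff cluster cutoff override (defaults to
#'   `cfg$cluster_cutoff`)
#' @return list with `partition` (data.table file/cluster), `models`,
#'   `blacklists`, `pairs`, `origins`, `n_origins`
#' @export
run_corpus <- function(genomes, cfg = qc_config(), freqs = NULL,
                       cutoff = cfg$cluster_cutoff) {
  if (length(genomes) < 2) stop("corpus mode requires >=2 genomes")
  ids <- names(genomes) %||% paste0("g", seq_along(genomes))
  names(genomes) <- ids

  sets <- lapply(genomes, position_set)
  m <- distance_matrix(sets)
  labels <- cluster_corpus(m, cutoff = cutoff)
  cluster_ids <- paste0("c", labels)
  partition <- data.table::data.table(file = ids, cluster = cluster_ids)

  models <- lapply(sort(unique(labels)), function(l) {
    profile_cluster(sets[labels == l], cluster_id = paste0("c", l),
                    floor = cfg$cluster_floor)
  })
  names(models) <- vapply(models, function(x) x$cluster_id, character(1))

  blacklists <- list()
  if (!is.null(freqs)) {
    for (cid in names(models)) {
      members <- genomes[cluster_ids == cid]
      blacklists[[cid]] <- build_blacklist(
        members, freqs, cluster_id = cid, z_crit = cfg$z_crit,
        n_min = cfg$z_n_min, offpanel_max = cfg$offpanel_max
      )
    }
  }

  idres <- distinct_origins(genomes, min_shared = cfg$identity_min_shared)
  list(partition = partition, models = models, blacklists = blacklists,
       pairs = idres$pairs, origins = idres$origins,
       n_origins = idres$n_origins)
}
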