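# One-command pipeline driver: annotate -> arrays -> symmetry -> junctions
# -> microsat, with per-stage toggles, artifact export and a MANIFEST of
# content hashes for provenance.

#' Build a pipeline configuration
#'
#' Defaults mirror the module-level defaults; unknown keys are rejected.
#' The effective configuration is written into the output directory by
#' [run_pipeline()].
#'
#' @param genome path to the genome FASTA (or a `DNAStringSet`).
#' @param library path to the consensus library FASTA (or a named list of
#'   [sat_family()] objects).
#' @param out_dir output directory.
#' @param ... overrides of the default parameters (see
#'   `pipeline_defaults()`).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, library, out_dir, ...) {
  cfg <- pipeline_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(over)] <- over
  cfg$genome <- genome
  cfg$library <- library
  cfg$out_dir <- out_dir
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @export
pipeline_defaults <- function() {
  list(genome = NULL, library = NULL, out_dir = NULL,
       min_identity = 70, min_qcov = 70, max_overlap_fraction = 0.1,
       min_tandem = 5L,
       window_radius = 200L, site_identity_threshold = 90,
       junction_families = NULL,   # c(major, minor); NULL = two largest
       adjacency_max_gap = 1000L, junction_pad = 250L,
       transition_identity_threshold = 90,
       microsat_motif = "AC", microsat_min_units = 5L,
       microsat_family = NULL,     # NULL = skip linkage
       microsat_link_gap = 100L,
       stages = c("annotate", "arrays", "symmetry", "junctions",
                  "microsat"),
       seed = 1L)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writes GFF3/BED/TSV/JSON artifacts
#' plus the effective configuration and a MANIFEST listing every output
#' file with its MD5 hash, and returns the in-memory results. Reruns with
#' an identical configuration produce byte-identical annotation outputs.
#'
#' @param config a [pipeline_config()].
#' @return List of class `pipeline_report` with one element per executed
#'   stage plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- if (is.character(config$genome)) load_sequences(config$genome)
  else config$genome
  families <- if (is.character(config$library)) {
    read_family_library(config$library)
  } else config$library
  report <- list()
  outputs <- character()
  emit <- function(writer, obj, name) {
    path <- file.path(config$out_dir, name)
    writer(obj, path)
    outputs <<- c(outputs, path)
  }
  cfg_dump <- config
  cfg_dump$genome <- if (is.character(config$genome)) config$genome
  else "<in-memory>"
  cfg_dump$library <- if (is.character(config$library)) config$library
  else "<in-memory>"
  jsonlite::write_json(unclass(cfg_dump),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  outputs <- c(outputs, file.path(config$out_dir, "config.json"))
  on <- function(stage) stage %in% config$stages

  hits <- NULL
  if (on("annotate")) {
    raw <- search_monomers(genome, families,
                           min_identity = config$min_identity,
                           min_qcov = config$min_qcov)
    hits <- resolve_overlaps(raw, config$max_overlap_fraction)
    summ <- summarize_annotation(hits, genome)
    gff <- hits
    gff$type <- "satellite_monomer"
    emit(write_gff3, gff, "monomers.gff3")
    emit(write_tsv, summ$per_family, "annotation_summary.tsv")
    report$annotate <- list(hits = hits, summary = summ)
  }

  arrays <- NULL
  if (on("arrays") && !is.null(hits)) {
    arrays <- build_arrays(hits, families)
    st <- array_stats(arrays)
    gff <- arrays$arrays
    gff$type <- "satellite_array"
    emit(write_gff3, gff, "arrays.gff3")
    emit(write_tsv, st$summary, "array_stats.tsv")
    for (fam in names(st$kde)) {
      if (!is.null(st$kde[[fam]])) {
        emit(write_tsv, st$kde[[fam]],
             sprintf("array_length_kde_%s.tsv", fam))
      }
    }
    report$arrays <- list(arrays = arrays, stats = st,
                          satellite = vapply(names(families), function(f) {
                            classify_satellite(f, arrays, config$min_tandem)
                          }, TRUE))
  }

  decomposition <- NULL
  if (on("symmetry") && !is.null(arrays)) {
    decomposition <- decompose_subarrays(arrays, families)
    metrics <- macrodyad_metrics(decomposition)
    sites <- extract_inversion_sites(decomposition$inversions, genome,
                                     config$window_radius)
    gff <- decomposition$subarrays
    gff$type <- "satellite_subarray"
    emit(write_gff3, gff, "subarrays.gff3")
    if (nrow(decomposition$inversions) > 0) {
      ig <- decomposition$inversions
      ig$start <- ig$position
      ig$end <- ig$position + 1L
      ig$strand <- "."
      ig$type <- "inversion_point"
      ig$position <- NULL
      emit(write_gff3, ig, "inversion_points.gff3")
    }
    emit(write_tsv, metrics$per_array, "macrodyad_per_array.tsv")
    emit(write_tsv, metrics$per_inversion, "macrodyad_per_inversion.tsv")
    report$symmetry <- list(decomposition = decomposition,
                            metrics = metrics, sites = sites)
  }

  if (on("junctions") && !is.null(arrays)) {
    fams <- config$junction_families
    if (is.null(fams)) {
      bp <- tapply(hits$end - hits$start, hits$family_id, sum)
      fams <- names(sort(bp, decreasing = TRUE))[1:2]
    }
    adj <- find_adjacencies(arrays, fams[1], fams[2],
                            config$adjacency_max_gap)
    junc <- extract_junctions(genome, adj, arrays, config$junction_pad)
    report$junctions <- list(families = fams, junctions = junc)
    if (nrow(junc) > 0) {
      # transition types are defined by the inter-array cores (the
      # transition elements proper), which are orientation-independent;
      # abutting arrays carry no element
      core_ok <- nchar(junc$core) >= 20L
      junc$type_label <- "TRANS_none"
      cls <- NULL
      if (any(core_ok)) {
        cls <- classify_transitions(junc$core[core_ok],
                                    config$transition_identity_threshold,
                                    seed = config$seed)
        junc$type_label[core_ok] <- cls$assignments
      }
      minor_arrays <- arrays$arrays[arrays$arrays$family_id == fams[2], ,
                                    drop = FALSE]
      census <- cassette_census(minor_arrays, junc,
                                if (is.null(decomposition))
                                  data.frame(array_id = character())
                                else decomposition$inversions)
      emit(write_tsv, junc[, setdiff(names(junc), c("sequence", "core"))],
           "junctions.tsv")
      if (!is.null(cls)) {
        emit(write_tsv, cls$clusters, "transition_clusters.tsv")
      }
      path <- file.path(config$out_dir, "cassette_census.json")
      jsonlite::write_json(list(venn = as.list(census$venn),
                                n_arrays = census$n_arrays,
                                type_labels = as.list(census$type_labels)),
                           path, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, path)
      report$junctions$clusters <- cls
      report$junctions$junctions <- junc
      report$junctions$census <- census
    }
  }

  if (on("microsat")) {
    runs <- find_dinuc_runs(genome, config$microsat_motif,
                            config$microsat_min_units)
    report$microsat <- list(runs = runs)
    if (!is.null(config$microsat_family) && !is.null(hits)) {
      linked <- link_runs(runs, hits, config$microsat_family,
                          config$microsat_link_gap)
      stats <- linkage_stats(linked)
      bed <- linked
      bed$name <- ifelse(is.na(bed$linked_family), "unlinked",
                         paste0("linked_", bed$linked_family))
      emit(write_bed, bed, "microsat_runs.bed")
      emit(write_tsv, stats$summary, "microsat_stats.tsv")
      report$microsat$linked <- linked
      report$microsat$stats <- stats
    } else {
      emit(write_bed, runs, "microsat_runs.bed")
    }
  }

  manifest <- data.frame(file = basename(outputs),
                         md5 = unname(tools::md5sum(outputs)),
                         stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$out_dir, "MANIFEST.tsv"))
  report$manifest <- manifest
  structure(report, class = "pipeline_report")
}
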