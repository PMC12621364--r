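#' Run the full synthetic trio generator
#'
#' Convenience wrapper chaining [simulate_trio_genomes()],
#' [simulate_annotations()] and [simulate_methylomes()] (annotations are
#' generated first so that forced gbM/teM gene classes are reflected in
#' the methylomes).
#'
#' @param config a [trio_config()].
#' @param annotations generate gene/repeat annotations (default `TRUE`).
#' @return list with `truth`, `graph` (unchopped), `annotations` (or
#'   `NULL`), `methylomes`.
#' @export
simulate_trio <- function(config, annotations = TRUE) {
  sim <- simulate_trio_genomes(config)
  ann <- if (annotations) simulate_annotations(sim$truth, config) else NULL
  meth <- simulate_methylomes(sim$truth, config, annotations = ann)
  list(truth = sim$truth, graph = sim$graph, annotations = ann,
       methylomes = meth)
}

#' Write a simulated trio to disk
#'
#' Materialises the study layout: chopped GFA graph, per-clone CX
#' reports, GFF3 gene models, BED repeats, a variant table and the
#' ground-truth tables (TSV).
#'
#' @param sim output of [simulate_trio()].
#' @param outdir output directory (created if needed).
#' @param chop_len node length for the written graph (default 200 bp).
#' @return `outdir`, invisibly.
#' @export
write_trio <- function(sim, outdir, chop_len = 200) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_gfa(chop_nodes(sim$graph, chop_len), file.path(outdir, "trio.gfa"))
  for (cv in names(sim$methylomes$tables)) {
    for (cl in names(sim$methylomes$tables[[cv]])) {
      write_cx_report(sim$methylomes$tables[[cv]][[cl]],
                      file.path(outdir, paste0(cl, ".CX_report.txt")))
    }
  }
  if (!is.null(sim$annotations)) {
    write_gff3(sim$annotations, file.path(outdir, "genes.gff3"))
    write_repeats_bed(sim$annotations$repeats,
                      file.path(outdir, "repeats.bed"))
    data.table::fwrite(sim$annotations$genes,
                       file.path(outdir, "gene_truth.tsv"), sep = "\t")
  }
  data.table::fwrite(sim$truth$variants, file.path(outdir, "variants.tsv"),
                     sep = "\t")
  data.table::fwrite(sim$methylomes$site_states,
                     file.path(outdir, "site_states.tsv"), sep = "\t")
  invisible(outdir)
}
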