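# Shared fixture loaders. The packaged reference is a synthetic
# miRBase-style set: faithful mature sequences, invented (but internally
# consistent) genomic placements preserving the real cluster composition.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "mirtraj")
  if (p == "") p <- file.path("..", "..", "inst", "extdata", file)
  p
}

load_fixture_reference <- function() {
  suppressWarnings(load_mirna_reference(fixture_path("mature_synthetic.fa"),
                                        fixture_path("loci_synthetic.gff3")))
}

load_fixture_contaminants <- function() {
  load_contaminants(fixture_path("contaminants_synthetic.fa"))
}

seed_of <- function(ann, id) ann$seed[match(id, ann$mirna_id)]
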