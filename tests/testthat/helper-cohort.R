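# Shared fixtures, built in code.

# small classified cohort from explicit strings
classify_strings <- function(strings, ...) {
  classify_cohort(tibble::tibble(karyotype = strings, ...))
}

# seeded synthetic cohort, failures dropped and classified
make_classified_cohort <- function(n, seed) {
  co <- generate_cohort(cohort_config(n_samples = n, seed = seed))
  classify_cohort(co[!is.na(co$karyotype), , drop = FALSE])
}

# all categories the generator can instantiate, with their mosaic forms
abnormal_categories <- function() {
  list(
    non_mosaic = c("aneuploidy", "robertsonian", "translocation", "derivative",
                   "inversion", "deletion", "duplication", "addition",
                   "isochromosome", "psu_dic", "triploid", "hermaphroditism",
                   "length_polymorphism"),
    mosaic = c("aneuploidy", "translocation", "derivative", "inversion",
               "deletion", "isochromosome")
  )
}
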