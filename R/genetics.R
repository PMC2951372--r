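#' Specify a genetic cross with seed-class predicates
#'
#' A cross is given by the parental genotypes (two alleles per locus) and a
#' predicate describing the seed class of interest. Each predicate entry is
#' either `zygotic_homozygous` (both inherited alleles must equal `allele`)
#' or `maternal` (the maternally transmitted allele must equal `allele`;
#' used for imprinted maternal-effect loci such as FIS2, where loss of the
#' maternal allele alone abolishes activity).
#'
#' @param mother named list; each element a length-2 character vector of
#'   alleles.
#' @param predicate named list over a subset of loci; each element
#'   `list(type = "maternal" | "zygotic_homozygous", allele = "<allele>")`.
#' @param father paternal genotype; defaults to `mother` (self-pollination).
#' @return object of class `cross_spec`.
#' @export
cross_spec <- function(mother, predicate, father = mother) {
  chk <- function(g, who) {
    if (!is.list(g) || is.null(names(g)) ||
        !all(vapply(g, length, 1L) == 2L))
      stopf("%s genotype must be a named list of length-2 allele vectors", who)
  }
  chk(mother, "maternal"); chk(father, "paternal")
  if (!is.list(predicate) || is.null(names(predicate)))
    stopf("predicate must be a named list")
  for (locus in names(predicate)) {
    if (!locus %in% names(mother) || !locus %in% names(father))
      stopf("predicate references missing locus '%s'", locus)
    p <- predicate[[locus]]
    if (!p$type %in% c("maternal", "zygotic_homozygous"))
      stopf("unknown predicate type '%s'", p$type)
  }
  structure(list(mother = mother, father = father, predicate = predicate),
            class = "cross_spec")
}

#' Expected fraction of seeds satisfying a cross predicate
#'
#' Exact probability by enumeration of parental gamete combinations, loci
#' segregating independently. Maternal-effect predicates are evaluated on the
#' maternally transmitted allele only; zygotic-homozygous predicates require
#' both transmitted alleles to match. For a selfed fis2/FIS2; met1/MET1
#' double heterozygote with the predicate (maternal fis2 allele, met1/met1),
#' this is 1/2 x 1/4 = 12.5 percent of seeds.
#'
#' @param cross a [cross_spec()].
#' @return the exact probability (numerator and denominator are exact powers
#'   of two for biallelic loci).
#' @export
expected_seed_fraction <- function(cross) {
  stopifnot(inherits(cross, "cross_spec"))
  prob <- 1
  for (locus in names(cross$predicate)) {
    p <- cross$predicate[[locus]]
    mg <- cross$mother[[locus]]  # maternal gametes, equally likely
    pg <- cross$father[[locus]]
    num <- 0L
    for (a in mg) for (b in pg) {
      ok <- switch(p$type,
                   maternal = a == p$allele,
                   zygotic_homozygous = a == p$allele && b == p$allele)
      if (ok) num <- num + 1L
    }
    prob <- prob * num / (length(mg) * length(pg))
  }
  prob
}
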