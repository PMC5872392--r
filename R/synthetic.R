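#' Configuration of the synthetic-data generator
#'
#' The generator emulates the qualitative structure of the real inputs:
#' herbs organised in modules that share an efficacy repertoire, proteins
#' organised in modules that share a pathway repertoire, and herb-target
#' links concentrated between coupled herb/protein module pairs. Under this
#' planted structure, herbs sharing efficacies share targets and proteins
#' sharing pathways share targeted herbs — the assumption the walk exploits
#' — so target recovery can be asserted end to end.
#'
#' The defaults (4 herb modules of 10 herbs with 5 efficacies each, 4
#' protein modules of 25 proteins with 5 pathways each, within-module link
#' probability 0.8 against a 0.02 background, identity module coupling)
#' give every herb roughly twenty targets, mirroring the scale of a real
#' herb's target repertoire while keeping a full evaluation run fast.
#'
#' @param n_herb_modules,herbs_per_module herb block structure.
#' @param efficacies_per_module efficacy labels private to each herb module.
#' @param n_protein_modules,proteins_per_module protein block structure.
#' @param pathways_per_module pathway labels private to each protein module.
#' @param within_module_link_prob probability of a within-module link
#'   (annotation links and coupled herb-target links).
#' @param background_link_prob probability of a herb-target link between
#'   uncoupled modules; must be below `within_module_link_prob`.
#' @param module_coupling integer vector mapping herb module -> protein
#'   module (default identity, recycled if needed).
#' @param rng_seed seed making the tables fully reproducible.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_herb_modules = 4, herbs_per_module = 10,
                         efficacies_per_module = 5,
                         n_protein_modules = 4, proteins_per_module = 25,
                         pathways_per_module = 5,
                         within_module_link_prob = 0.8,
                         background_link_prob = 0.02,
                         module_coupling = NULL,
                         rng_seed = 1L) {
  stopifnot(n_herb_modules >= 1, herbs_per_module >= 1,
            efficacies_per_module >= 1, n_protein_modules >= 1,
            proteins_per_module >= 1, pathways_per_module >= 1,
            within_module_link_prob >= 0, within_module_link_prob <= 1,
            background_link_prob >= 0, background_link_prob <= 1,
            background_link_prob < within_module_link_prob)
  if (is.null(module_coupling)) {
    module_coupling <- rep_len(seq_len(n_protein_modules), n_herb_modules)
  }
  stopifnot(length(module_coupling) == n_herb_modules,
            all(module_coupling %in% seq_len(n_protein_modules)))
  structure(
    list(n_herb_modules = n_herb_modules,
         herbs_per_module = herbs_per_module,
         efficacies_per_module = efficacies_per_module,
         n_protein_modules = n_protein_modules,
         proteins_per_module = proteins_per_module,
         pathways_per_module = pathways_per_module,
         within_module_link_prob = within_module_link_prob,
         background_link_prob = background_link_prob,
         module_coupling = module_coupling,
         rng_seed = rng_seed),
    class = "synth_config"
  )
}

#' Generate synthetic association tables with planted modules
#'
#' Draws the three tables of the pipeline from a [synth_config()]: each herb
#' links to each efficacy of its module with the within-module probability
#' (at least one link is guaranteed so no herb is unannotated), proteins
#' link to their module's pathways likewise, and herb-target links are drawn
#' with the within-module probability between coupled modules and the
#' background probability elsewhere (at least one target per herb
#' guaranteed). Fully reproducible from `rng_seed`.
#'
#' @param cfg a [synth_config()].
#' @return A list with `herb_efficacy`, `protein_pathway`, `herb_target`
#'   association tables and `truth` (herb/protein module assignments and
#'   the coupling map).
#' @export
generate_tables <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(cfg$rng_seed, {
    herbs <- sprintf("herb%03d", seq_len(cfg$n_herb_modules *
                                           cfg$herbs_per_module))
    herb_module <- rep(seq_len(cfg$n_herb_modules),
                       each = cfg$herbs_per_module)
    proteins <- sprintf("prot%03d", seq_len(cfg$n_protein_modules *
                                              cfg$proteins_per_module))
    prot_module <- rep(seq_len(cfg$n_protein_modules),
                       each = cfg$proteins_per_module)
    efficacies <- sprintf("eff%02d_m%d",
                          sequence(rep(cfg$efficacies_per_module,
                                       cfg$n_herb_modules)),
                          rep(seq_len(cfg$n_herb_modules),
                              each = cfg$efficacies_per_module))
    eff_module <- rep(seq_len(cfg$n_herb_modules),
                      each = cfg$efficacies_per_module)
    pathways <- sprintf("path%02d_m%d",
                        sequence(rep(cfg$pathways_per_module,
                                     cfg$n_protein_modules)),
                        rep(seq_len(cfg$n_protein_modules),
                            each = cfg$pathways_per_module))
    path_module <- rep(seq_len(cfg$n_protein_modules),
                       each = cfg$pathways_per_module)

    he <- draw_block_links(herbs, herb_module, efficacies, eff_module,
                           cfg$within_module_link_prob, 0)
    pp <- draw_block_links(proteins, prot_module, pathways, path_module,
                           cfg$within_module_link_prob, 0)
    ht <- draw_block_links(herbs, cfg$module_coupling[herb_module],
                           proteins, prot_module,
                           cfg$within_module_link_prob,
                           cfg$background_link_prob)

    list(
      herb_efficacy = association_table(he$entity, he$attribute),
      protein_pathway = association_table(pp$entity, pp$attribute),
      herb_target = association_table(ht$entity, ht$attribute),
      truth = list(herb_module = stats::setNames(herb_module, herbs),
                   protein_module = stats::setNames(prot_module, proteins),
                   module_coupling = cfg$module_coupling)
    )
  })
}

# Bernoulli links between entities and attributes: within-module pairs use
# p_within, the rest p_background; every entity is guaranteed >= 1 link
# (falling back to a random within-module attribute).
draw_block_links <- function(entities, e_module, attributes, a_module,
                             p_within, p_background) {
  out_e <- character()
  out_a <- character()
  for (i in seq_along(entities)) {
    p <- ifelse(a_module == e_module[i], p_within, p_background)
    hit <- stats::runif(length(attributes)) < p
    if (!any(hit)) {
      within <- which(a_module == e_module[i])
      hit[if (length(within)) sample(within, 1) else
        sample(length(attributes), 1)] <- TRUE
    }
    out_e <- c(out_e, rep(entities[i], sum(hit)))
    out_a <- c(out_a, attributes[hit])
  }
  data.frame(entity = out_e, attribute = out_a, stringsAsFactors = FALSE)
}

#' Shuffle the herb-target links of a dataset (negative control)
#'
#' Keeps each herb's target count but redraws its targets uniformly from
#' the protein universe, destroying the planted module coupling. Used as
#' the label-permuted control that a working predictor must beat.
#'
#' @param ht herb-target [association_table()].
#' @param rng_seed RNG seed.
#' @return A shuffled `assoc_table` over the same entities/attributes.
#' @export
shuffle_links <- function(ht, rng_seed = NULL) {
  stopifnot(inherits(ht, "assoc_table"))
  with_seed(rng_seed, {
    degrees <- table(ht$pairs$entity)[ht$entities]
    ent <- rep(ht$entities, times = degrees)
    att <- unlist(lapply(degrees, function(d) sample(ht$attributes, d)),
                  use.names = FALSE)
    out <- association_table(ent, att)
    out$attributes <- ht$attributes
    out
  })
}

#' Write the synthetic tables (plus truth) to a directory
#'
#' @param tables a [generate_tables()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synth_tables <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_association_table(tables$herb_efficacy,
                          file.path(dir, "herb_efficacy.tsv"))
  write_association_table(tables$protein_pathway,
                          file.path(dir, "protein_pathway.tsv"))
  write_association_table(tables$herb_target,
                          file.path(dir, "herb_target.tsv"))
  truth <- tables$truth
  utils::write.table(
    data.frame(id = c(names(truth$herb_module), names(truth$protein_module)),
               type = c(rep("herb", length(truth$herb_module)),
                        rep("protein", length(truth$protein_module))),
               module = c(truth$herb_module, truth$protein_module)),
    file.path(dir, "truth.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(dir)
}
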