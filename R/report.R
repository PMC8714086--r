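# One-command study-style report: runs every analysis stage in dependency
# order on a pedigree and writes a directory of delimited tables plus a
# JSON index. The relationship matrix is computed once and shared across
# stages (it dominates cost); every value in the index is the output of the
# corresponding module function, never recomputed here.

.fmt_pct <- function(x) list(fraction = signif(x, 4), percent = signif(100 * x, 4))

.write_tsv <- function(df, dir, name) {
  utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full diversity analysis and write a report directory
#'
#' Stages: validation, pedigree completeness (pedigree file and reference
#' population), kinship-derived parameters (F, AR, individual increases,
#' inbreeding classes, both Ne estimators), generation intervals (both
#' offspring-selection modes), gene-origin parameters with the
#' diversity-loss partition (pedigree file and reference population),
#' subpopulation structure (co-ancestry means, FST, UPGMA tree, PCA,
#' heatmap matrix) and the AR-based mating plan. When no reference flag is
#' present the reference-specific stages fall back to the whole pedigree
#' with a warning. Output is deterministic given the input and `seed`.
#'
#' @param ped a `pedigree`.
#' @param dir output directory (created if absent).
#' @param seed seed for the stochastic stages (gene drop).
#' @param pci_depth completeness index depth.
#' @param genedrop_replicates gene-drop replicates.
#' @param ar_low,ar_high AR thresholds for the mating groups.
#' @param max_kinship kinship ceiling for pair recommendation.
#' @return A `study_report` list, invisibly; side effect: tables, Newick
#'   tree, `index.json` and `log.txt` under `dir`.
#' @export
full_report <- function(ped, dir, seed = 1, pci_depth = 5,
                        genedrop_replicates = 10000,
                        ar_low = 0.04, ar_high = 0.125, max_kinship = 0.0625) {
  stopifnot(is_pedigree(ped))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("stage %-12s %.2fs", name, proc.time()[["elapsed"]] - t0))
    note("stage %s: done", name)
    out
  }

  all_ids <- ped$id[!ped$phantom]
  ref <- reference_ids(ped)
  if (length(ref) == 0) {
    warning("no reference flag present; reference stages use the whole pedigree")
    note("no reference flag; using all %d animals", length(all_ids))
    ref <- all_ids
  }

  val <- stage("validate", validate_pedigree(ped, "permissive"))
  validation_report_json(val, file.path(dir, "validation.json"))

  comp <- stage("completeness", {
    tab <- completeness(ped, depth = pci_depth)
    .write_tsv(tab, dir, "completeness.tsv")
    prof_all <- completeness_profile(ped, all_ids)
    prof_ref <- completeness_profile(ped, ref)
    .write_tsv(data.frame(generation = prof_all$generation,
                          pedigree_file = prof_all$prop_known,
                          reference = prof_ref$prop_known),
               dir, "completeness_profile.tsv")
    list(table = tab, profile_all = prof_all, profile_ref = prof_ref)
  })

  ks <- stage("kinship", relationship_matrix(ped))
  sex <- stats::setNames(ped$sex[!ped$phantom], all_ids)
  kin <- stage("diversity", {
    tab <- data.frame(id = all_ids, sex = sex[all_ids],
                      F = ks$F[all_ids], AR = ks$AR[all_ids],
                      dF = ks$dF[all_ids], t = ks$t[all_ids],
                      is_reference = all_ids %in% ref,
                      stringsAsFactors = FALSE)
    .write_tsv(tab, dir, "diversity.tsv")
    grp_means <- function(ids) {
      list(F = .fmt_pct(mean(ks$F[ids])), AR = .fmt_pct(mean(ks$AR[ids])),
           dF = .fmt_pct(mean(ks$dF[ids], na.rm = TRUE)),
           F_male = .fmt_pct(mean(ks$F[ids[sex[ids] == "male"]])),
           F_female = .fmt_pct(mean(ks$F[ids[sex[ids] == "female"]])),
           AR_male = .fmt_pct(mean(ks$AR[ids[sex[ids] == "male"]])),
           AR_female = .fmt_pct(mean(ks$AR[ids[sex[ids] == "female"]])))
    }
    classes <- list(pedigree_file = inbreeding_classes(ks$F[all_ids], sex[all_ids]),
                    reference = inbreeding_classes(ks$F[ref], sex[ref]))
    .write_tsv(classes$pedigree_file, dir, "inbreeding_classes_pf.tsv")
    .write_tsv(classes$reference, dir, "inbreeding_classes_rp.tsv")
    list(table = tab, classes = classes,
         means = list(pedigree_file = grp_means(all_ids),
                      reference = grp_means(ref)))
  })

  ne <- stage("ne", ne_estimates(ped, ref))

  ints <- stage("intervals", {
    out <- list(all = generation_intervals(ped, "all"),
                reproducers = generation_intervals(ped, "reproducers"))
    .write_tsv(as.data.frame(out$all), dir, "intervals_all.tsv")
    .write_tsv(as.data.frame(out$reproducers), dir, "intervals_reproducers.tsv")
    note("interval exclusions (all): %s",
         paste(names(attr(out$all, "exclusions")),
               attr(out$all, "exclusions"), sep = "=", collapse = ", "))
    out
  })

  go <- stage("gene_origin", {
    out <- list(pedigree_file = gene_origin_report(ped, all_ids,
                                                   replicates = genedrop_replicates,
                                                   seed = seed),
                reference = gene_origin_report(ped, ref,
                                               replicates = genedrop_replicates,
                                               seed = seed + 1))
    tab <- do.call(rbind, lapply(names(out), function(nm) {
      g <- out[[nm]]
      data.frame(population = nm, n = g$n_ref, f = g$f,
                 fe = g$fe, fa = g$fa, fg = g$fg_coancestry,
                 fg_genedrop = g$fg_genedrop, n50 = g$n50)
    }))
    .write_tsv(tab, dir, "gene_origin.tsv")
    out
  })

  st <- stage("structure", {
    srep <- structure_report(ped, ref)
    .write_tsv(cbind(group = rownames(srep$fst), as.data.frame(srep$fst)),
               dir, "fst.tsv")
    if (!is.null(srep$dendrogram))
      writeLines(srep$dendrogram$newick, file.path(dir, "fst_tree.nwk"))
    .write_tsv(data.frame(id = rownames(srep$pca$coords), srep$pca$coords),
               dir, "pca.tsv")
    .write_tsv(data.frame(component = seq_along(srep$pca$var_explained),
                          var_explained = srep$pca$var_explained),
               dir, "pca_scree.tsv")
    .write_tsv(cbind(id = rownames(srep$heatmap$matrix),
                     as.data.frame(srep$heatmap$matrix)),
               dir, "heatmap.tsv")
    srep
  })

  mat <- stage("mating", {
    groups <- classify_by_ar(ks$AR[ref], low = ar_low, high = ar_high)
    pairs <- recommend_pairs(ped, candidates = groups$group1,
                             max_kinship = max_kinship)
    gtab <- data.frame(
      group = c("AR<low", "low<=AR<=high", "AR>high"),
      n = c(length(groups$group1), length(groups$group2), length(groups$group3)),
      ids = c(paste(groups$group1, collapse = ";"),
              paste(groups$group2, collapse = ";"),
              paste(groups$group3, collapse = ";")))
    .write_tsv(gtab, dir, "mating_groups.tsv")
    .write_tsv(as.data.frame(pairs), dir, "mating_pairs.tsv")
    list(groups = groups, pairs = pairs)
  })

  index <- list(
    n_animals = length(all_ids),
    n_reference = length(ref),
    n_founders = length(founder_ids(ped)),
    completeness = list(
      pci_gen1_reference = .fmt_pct(comp$profile_ref$prop_known[1]),
      mean_max_gen = mean(comp$table$max_gen),
      mean_full_gen = mean(comp$table$full_gen),
      mean_equiv_gen = mean(comp$table$equiv_gen)),
    diversity = kin$means,
    ne = list(ne_deltaF = ne$ne_deltaF, ne_coancestry = ne$ne_coancestry,
              n_used = as.list(ne$n_used)),
    intervals = list(
      total_mean_all = ints$all$mean[ints$all$pathway == "total"],
      total_mean_reproducers =
        ints$reproducers$mean[ints$reproducers$pathway == "total"]),
    gene_origin = lapply(go, function(g)
      list(n = g$n_ref, f = g$f, fe = g$fe, fa = g$fa,
           fg = g$fg_coancestry, fg_genedrop = g$fg_genedrop, n50 = g$n50,
           loss_total = .fmt_pct(g$loss$loss_total),
           loss_founder = .fmt_pct(g$loss$loss_founder),
           loss_drift = .fmt_pct(g$loss$loss_drift))),
    structure = list(
      n_groups = nrow(st$fst),
      fst_estimator = st$estimator,
      pc12_var_explained = .fmt_pct(sum(st$pca$var_explained[1:2]))),
    mating = list(n_group1 = length(mat$groups$group1),
                  n_group2 = length(mat$groups$group2),
                  n_group3 = length(mat$groups$group3),
                  n_pairs = nrow(mat$pairs)),
    seed = seed)
  writeLines(jsonlite::toJSON(index, auto_unbox = TRUE, digits = 10,
                              pretty = TRUE, null = "null"),
             file.path(dir, "index.json"))
  writeLines(log_lines, file.path(dir, "log.txt"))

  invisible(structure(list(validation = val, completeness = comp,
                           kinship = ks, diversity = kin, ne = ne,
                           intervals = ints, gene_origin = go,
                           structure = st, mating = mat, index = index),
                      class = "study_report"))
}
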