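# Synthetic multi-strain world: gene repertoires with core/accessory/rare
# families and allele variation, a toy universal catabolic network whose
# per-strain gene content determines true substrate phenotypes, and simulated
# phenotype-microarray plates. Full ground truth is retained so every
# downstream stage can be scored.

#' Configuration of a synthetic multi-strain world
#'
#' Defaults describe a small but realistic desk-scale panel: 8 strains, a
#' core genome of 20 families plus 15 accessory and 4 strain-unique (rare)
#' families, reference proteins of 150-400 residues (typical bacterial
#' protein sizes), 2% amino-acid substitutions per site per strain, six carbon
#' substrates each catabolized by a linear 2-3 reaction pathway (the first
#' substrate, glucose, is gated by core families so every strain grows on
#' it), and 48-hour kinetic traces read every 30 minutes.
#'
#' @param n_strains number of strains.
#' @param n_core_families gene families present in every strain.
#' @param n_accessory_families families present in each strain independently
#'   with `accessory_presence_prob`.
#' @param n_rare_families families present in exactly one (random) strain.
#' @param accessory_presence_prob per-strain presence probability of each
#'   accessory family.
#' @param allele_mutation_rate amino-acid substitutions per site per strain.
#' @param protein_length_range `(min, max)` residues of family reference
#'   proteins.
#' @param n_substrates number of carbon substrates assayed.
#' @param n_pathways number of catabolic pathways (`<= n_substrates`;
#'   pathway i degrades substrate i; substrates beyond `n_pathways` support
#'   no growth).
#' @param pathway_length_range `(min, max)` reactions per pathway.
#' @param grower_signal_amplitude plateau signal of a growing well
#'   (arbitrary OmniLog-like units).
#' @param baseline_signal baseline signal of blank and non-growing wells.
#' @param noise_sd standard deviation of i.i.d. Gaussian signal noise
#'   (`0` gives the noiseless limit).
#' @param n_timepoints number of evenly spaced reads per well.
#' @param total_hours assay duration in hours.
#' @param n_replicates replicate kinetic plates per strain (default 3,
#'   the triplicate-plate protocol).
#' @param n_control_wells blank negative-control wells per plate.
#' @param mutation_profile `"uniform"` draws substitutions uniformly over the
#'   19 alternative residues; `"conservative"` restricts them to the same
#'   physico-chemical group (used for stress-testing substitution profiling).
#' @param allow_indels if `TRUE`, each mutated protein may additionally gain
#'   a single-residue insertion or deletion (stress-test switch; default off
#'   so alleles stay length-matched).
#' @param seed root random seed; all stages draw from named child streams.
#' @return a `world_config` list.
#' @export
world_config <- function(n_strains = 8,
                         n_core_families = 20,
                         n_accessory_families = 15,
                         n_rare_families = 4,
                         accessory_presence_prob = 0.6,
                         allele_mutation_rate = 0.02,
                         protein_length_range = c(150, 400),
                         n_substrates = 6,
                         n_pathways = 6,
                         pathway_length_range = c(2, 3),
                         grower_signal_amplitude = 200,
                         baseline_signal = 10,
                         noise_sd = 5,
                         n_timepoints = 97,
                         total_hours = 48,
                         n_replicates = 3,
                         n_control_wells = 3,
                         mutation_profile = c("uniform", "conservative"),
                         allow_indels = FALSE,
                         seed = 1L) {
  assert_count(n_strains, "n_strains")
  assert_count(n_core_families, "n_core_families")
  assert_count(n_accessory_families, "n_accessory_families", min = 0L)
  assert_count(n_rare_families, "n_rare_families", min = 0L)
  assert_prob(accessory_presence_prob, "accessory_presence_prob")
  assert_prob(allele_mutation_rate, "allele_mutation_rate")
  assert_range(protein_length_range, "protein_length_range", min = 5)
  assert_count(n_substrates, "n_substrates")
  assert_count(n_pathways, "n_pathways")
  assert_range(pathway_length_range, "pathway_length_range", min = 1)
  assert_count(n_timepoints, "n_timepoints", min = 2L)
  assert_count(n_replicates, "n_replicates")
  assert_count(n_control_wells, "n_control_wells")
  assert_count(seed, "seed", min = 0L)
  mutation_profile <- match.arg(mutation_profile)
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0")
  if (grower_signal_amplitude < baseline_signal) {
    abort("`grower_signal_amplitude` must be >= `baseline_signal`")
  }
  if (total_hours <= 0) abort("`total_hours` must be positive")
  if (n_pathways > n_substrates) {
    abort("`n_pathways` must not exceed `n_substrates`")
  }
  if (pathway_length_range[2] > n_core_families) {
    abort("the core-gated glucose pathway needs at most `n_core_families` reactions")
  }
  if ((n_pathways - 1L) * pathway_length_range[2] > n_accessory_families) {
    abort(paste0("contradictory configuration: more pathway reactions than ",
                 "accessory families available to gate them (each accessory ",
                 "pathway reaction needs its own family)"))
  }
  structure(
    list(n_strains = as.integer(n_strains),
         n_core_families = as.integer(n_core_families),
         n_accessory_families = as.integer(n_accessory_families),
         n_rare_families = as.integer(n_rare_families),
         accessory_presence_prob = accessory_presence_prob,
         allele_mutation_rate = allele_mutation_rate,
         protein_length_range = as.integer(protein_length_range),
         n_substrates = as.integer(n_substrates),
         n_pathways = as.integer(n_pathways),
         pathway_length_range = as.integer(pathway_length_range),
         grower_signal_amplitude = grower_signal_amplitude,
         baseline_signal = baseline_signal,
         noise_sd = noise_sd,
         n_timepoints = as.integer(n_timepoints),
         total_hours = total_hours,
         n_replicates = as.integer(n_replicates),
         n_control_wells = as.integer(n_control_wells),
         mutation_profile = mutation_profile,
         allow_indels = isTRUE(allow_indels),
         seed = as.integer(seed)),
    class = "world_config"
  )
}

#' Generate a synthetic multi-strain world with full ground truth
#'
#' Core families appear in every strain, accessory families independently
#' with `accessory_presence_prob`, rare families in exactly one strain. Each
#' family has a reference protein; each strain's copy is mutated at
#' `allele_mutation_rate` (substitutions only by default). Catabolic pathways
#' are linear reaction chains from a substrate exchange to a common biomass
#' precursor; every pathway reaction is gated by a GPR referencing one
#' family, and each accessory pathway reaction is gated by a *distinct*
#' accessory family, so losing one family breaks exactly one substrate.
#' True phenotypes are asserted self-consistent with FBA on the
#' strain-restricted universal network at generation time.
#'
#' @param config a [world_config()].
#' @return a `synthetic_world`: list with `strains`, `proteomes` (tibble:
#'   strain, gene, sequence), `gene_family_truth` (tibble: strain, gene,
#'   family), `universal_network`, `true_gene_content` (strain -> family-gene
#'   set), `substrate_exchanges` (substrate -> exchange id),
#'   `true_phenotype` (tibble: strain, substrate, call), `truth_presence`
#'   (binary strain x family matrix over carried families), `plate_readings`
#'   (long tibble), `pathway_gating`, and `config`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  strains <- sprintf("S%02d", seq_len(config$n_strains))
  fam_type <- rep(c("core", "accessory", "rare"),
                  c(config$n_core_families, config$n_accessory_families,
                    config$n_rare_families))
  families <- c(sprintf("C%03d", seq_len(config$n_core_families)),
                if (config$n_accessory_families > 0)
                  sprintf("A%03d", seq_len(config$n_accessory_families)),
                if (config$n_rare_families > 0)
                  sprintf("R%03d", seq_len(config$n_rare_families)))

  # -- family presence (stream: genomes) --------------------------------------
  presence <- with_stream_seed(config$seed, "genomes", {
    m <- matrix(0L, nrow = length(strains), ncol = length(families),
                dimnames = list(strains, families))
    m[, fam_type == "core"] <- 1L
    for (j in which(fam_type == "accessory")) {
      m[, j] <- rbinom(length(strains), 1L, config$accessory_presence_prob)
    }
    for (j in which(fam_type == "rare")) {
      m[sample(length(strains), 1L), j] <- 1L
    }
    m
  })

  # -- reference proteins (stream: proteins) ----------------------------------
  reference <- with_stream_seed(config$seed, "proteins", {
    lens <- sample(seq(config$protein_length_range[1],
                       config$protein_length_range[2]),
                   length(families), replace = TRUE)
    setNames(vapply(lens, function(L) {
      paste(sample(AA_ALPHABET20, L, replace = TRUE), collapse = "")
    }, character(1)), families)
  })

  # -- per-strain alleles (stream: alleles) -----------------------------------
  proteome_rows <- with_stream_seed(config$seed, "alleles", {
    rows <- list()
    for (s in strains) {
      carried <- families[presence[s, ] == 1L]
      gi <- 0L
      for (f in carried) {
        gi <- gi + 1L
        rows[[length(rows) + 1L]] <- list(
          strain = s,
          gene = sprintf("%s_g%03d", s, gi),
          family = f,
          sequence = mutate_protein(reference[[f]],
                                    rate = config$allele_mutation_rate,
                                    profile = config$mutation_profile,
                                    allow_indels = config$allow_indels))
      }
    }
    bind_rows(lapply(rows, as_tibble))
  })

  # -- universal catabolic network (stream: network) --------------------------
  net <- with_stream_seed(config$seed, "network", {
    build_toy_network(config, families, fam_type)
  })

  # -- ground-truth phenotypes ------------------------------------------------
  substrates <- names(net$substrate_exchanges)
  gating <- net$pathway_gating # substrate -> character vector of gating families
  true_phenotype <- tidyr::expand_grid(strain = strains, substrate = substrates)
  true_phenotype$call <- purrr::pmap_lgl(true_phenotype, function(strain, substrate) {
    g <- gating[[substrate]]
    if (is.null(g)) return(FALSE) # substrate without a pathway
    all(presence[strain, g] == 1L)
  })

  # self-consistency: FBA on the strain-restricted universal network must
  # reproduce the gating-rule phenotype for every (strain, substrate)
  model_genes <- intersect(families, net$network$genes)
  for (s in strains) {
    present_genes <- model_genes[presence[s, model_genes] == 1L]
    sub_net <- restrict_network(net$network, present_genes)$network
    for (cs in substrates) {
      ex_id <- net$substrate_exchanges[[cs]]
      grows <- if (is.na(ex_id)) FALSE else {
        fba(sub_net, carbon_source = ex_id, uptake = 10)$growth
      }
      truth <- true_phenotype$call[true_phenotype$strain == s &
                                     true_phenotype$substrate == cs]
      if (!identical(grows, truth)) {
        abort(sprintf("world self-consistency failed for (%s, %s)", s, cs))
      }
    }
  }

  truth_presence <- presence[, colSums(presence) > 0, drop = FALSE]

  world <- structure(
    list(strains = strains,
         proteomes = select(proteome_rows, "strain", "gene", "sequence"),
         gene_family_truth = select(proteome_rows, "strain", "gene", "family"),
         reference_proteins = reference,
         universal_network = net$network,
         substrate_exchanges = net$substrate_exchanges,
         pathway_gating = gating,
         true_gene_content = split(proteome_rows$family, proteome_rows$strain),
         true_phenotype = true_phenotype,
         truth_presence = truth_presence,
         plate_readings = NULL,
         config = config),
    class = "synthetic_world"
  )
  world$plate_readings <- generate_plate_traces(world, config)
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world> %d strains, %d gene families (%d carried), ",
                     "%d substrates, %d plate traces\n"),
              length(x$strains), length(x$reference_proteins),
              ncol(x$truth_presence), length(x$substrate_exchanges),
              nrow(distinct(x$plate_readings, .data$strain, .data$replicate,
                            .data$well))))
  invisible(x)
}

# point substitutions at `rate` per site; optional single-residue indel
mutate_protein <- function(seq, rate, profile = "uniform", allow_indels = FALSE) {
  aa <- strsplit(seq, "")[[1]]
  n_mut <- rbinom(1L, length(aa), rate)
  if (n_mut > 0) {
    pos <- sample(length(aa), n_mut)
    for (p in pos) {
      alt <- if (profile == "conservative") {
        setdiff(AA_GROUPS[[aa_group_of(aa[p])]], aa[p])
      } else {
        setdiff(AA_ALPHABET20, aa[p])
      }
      if (length(alt)) aa[p] <- sample(alt, 1L)
    }
  }
  if (allow_indels && runif(1) < rate) {
    if (runif(1) < 0.5 && length(aa) > 5) {
      aa <- aa[-sample(length(aa), 1L)]
    } else {
      at <- sample(length(aa), 1L)
      aa <- append(aa, sample(AA_ALPHABET20, 1L), after = at)
    }
  }
  paste(aa, collapse = "")
}

# Linear catabolic chains: EX_<sub>_e -> transport/first step -> ... -> bmp_c,
# plus a biomass sink consuming the common precursor. Pathway 1 ("glc") is
# gated by core families; pathways 2..P each consume distinct accessory
# families so one lost family breaks exactly one substrate.
build_toy_network <- function(config, families, fam_type) {
  substrates <- c("glc", if (config$n_substrates > 1)
    sprintf("cs%02d", seq(2, config$n_substrates)))
  lengths_ <- sample(seq(config$pathway_length_range[1],
                         config$pathway_length_range[2]),
                     config$n_pathways, replace = TRUE)
  core_ids <- families[fam_type == "core"]
  acc_ids <- families[fam_type == "accessory"]
  acc_pool <- sample(acc_ids) # shuffled; consumed left to right
  gating <- list()
  mets <- list(list(id = "bmp_c", compartment = "c"))
  rxns <- list()
  used_acc <- 0L
  for (i in seq_len(config$n_pathways)) {
    sub <- substrates[i]
    L <- lengths_[i]
    gate <- if (i == 1L) {
      core_ids[seq_len(L)]
    } else {
      g <- acc_pool[used_acc + seq_len(L)]
      used_acc <- used_acc + L
      g
    }
    gating[[sub]] <- gate
    ext <- paste0(sub, "_e")
    mets[[length(mets) + 1L]] <- list(id = ext, compartment = "e")
    chain <- c(ext,
               if (L > 1) paste0(sub, "_m", seq_len(L - 1), "_c"),
               "bmp_c")
    for (m in chain[-c(1, length(chain))]) {
      mets[[length(mets) + 1L]] <- list(id = m, compartment = "c")
    }
    rxns[[length(rxns) + 1L]] <- list(
      id = paste0("EX_", sub, "_e"),
      stoich = setNames(-1, ext), lb = 0, ub = BOUND_CAP,
      gpr = "", subsystem = "exchange")
    for (j in seq_len(L)) {
      rxns[[length(rxns) + 1L]] <- list(
        id = sprintf("%s_r%d", toupper(sub), j),
        stoich = setNames(c(-1, 1), c(chain[j], chain[j + 1])),
        lb = 0, ub = BOUND_CAP,
        gpr = gate[j],
        subsystem = sprintf("pathway_%s", sub))
    }
  }
  rxns[[length(rxns) + 1L]] <- list(
    id = "BIOMASS", stoich = c(bmp_c = -1), lb = 0, ub = BOUND_CAP,
    gpr = "", subsystem = "biomass")
  met_tbl <- bind_rows(lapply(mets, as_tibble)) |> distinct()
  rxn_tbl <- tibble(
    id = map_chr(rxns, "id"),
    lower_bound = map_dbl(rxns, "lb"),
    upper_bound = map_dbl(rxns, "ub"),
    subsystem = map_chr(rxns, "subsystem"),
    gpr = map_chr(rxns, "gpr"),
    stoichiometry = map(rxns, "stoich")
  )
  genes <- unique(unlist(gating))
  network <- metabolic_network(met_tbl, rxn_tbl, genes, objective = "BIOMASS")
  exch <- setNames(paste0("EX_", substrates[seq_len(config$n_pathways)], "_e"),
                   substrates[seq_len(config$n_pathways)])
  # substrates beyond n_pathways are assayed but have no pathway or exchange
  all_exch <- setNames(rep(NA_character_, length(substrates)), substrates)
  all_exch[names(exch)] <- exch
  list(network = network, substrate_exchanges = all_exch,
       pathway_gating = gating)
}
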