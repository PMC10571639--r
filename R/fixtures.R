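# Deterministic synthetic-data generator: an ontology with a vaccine
# subtree, a noisy mention corpus with gold mappings, and a registry-style
# interventions table. Everything every other module needs to run end to
# end with no download.

#' Noise configuration for synthetic mentions
#'
#' Each probability switches on one noise phenomenon observed in real
#' intervention strings: product-name parentheticals ("... (Bramix ®)"),
#' placebo suffixes (annotated as the vaccine itself), mentions naming two
#' products at once (gold maps to both), initials-style abbreviations,
#' dose/lot tokens, single-character misspellings, and an out-of-vocabulary
#' fraction whose gold concept is absent from the graph.
#'
#' Defaults are modest rates chosen to exercise every branch on a
#' 200-mention corpus while leaving most mentions near-verbatim, which is
#' how registry intervention names behave.
#'
#' @param p_product_parenthetical,p_placebo_suffix,p_multi_concept,p_abbreviation,p_dose_noise,p_misspell,oov_rate
#'   probabilities in `[0, 1]`.
#' @param seed integer RNG seed.
#' @return list of class `noise_config`.
#' @export
noise_config <- function(p_product_parenthetical = 0.2,
                         p_placebo_suffix = 0.15,
                         p_multi_concept = 0.1,
                         p_abbreviation = 0.1,
                         p_dose_noise = 0.25,
                         p_misspell = 0.05,
                         oov_rate = 0.03,
                         seed = 1L) {
  cfg <- list(
    p_product_parenthetical = p_product_parenthetical,
    p_placebo_suffix = p_placebo_suffix,
    p_multi_concept = p_multi_concept,
    p_abbreviation = p_abbreviation,
    p_dose_noise = p_dose_noise,
    p_misspell = p_misspell,
    oov_rate = oov_rate,
    seed = as.integer(seed)
  )
  probs <- unlist(cfg[names(cfg) != "seed"])
  if (any(probs < 0 | probs > 1)) {
    stop_("noise_config(): probabilities must lie in [0, 1]")
  }
  structure(cfg, class = "noise_config")
}

# Pronounceable unique stems ("zorel", "mabet", ...) used for synthetic
# labels and brand names; deterministic under the ambient RNG state.
make_stems <- function(n) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vows <- c("a", "e", "i", "o", "u")
  gen <- function(m) {
    vapply(seq_len(m), function(i) {
      paste0(sample(cons, 1), sample(vows, 1),
             sample(cons, 1), sample(vows, 1), sample(cons, 1))
    }, "")
  }
  stems <- gen(n)
  while (anyDuplicated(stems)) {
    dup <- which(duplicated(stems))
    stems[dup] <- gen(length(dup))
  }
  stems
}

cap1 <- function(x) {
  paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))
}

#' Generate a synthetic concept graph
#'
#' Builds a DAG emulating a mixed ontology: a vaccine subtree (root label
#' "vaccine", `is_vaccine` on every node) whose second level carries vaccine
#' class labels ("conjugate vaccine", ...) and whose deeper nodes nest a
#' synthetic stem onto the parent label ("zorel conjugate vaccine"), plus a
#' separate non-vaccine subtree of assay-style distractors. Nodes at depth
#' three or more carry a brand-style product synonym; every seventh deep
#' node gets a second parent, so the hierarchy is a genuine DAG. Subtree
#' depth grows logarithmically with `n_vaccine` at the given branching
#' factor (7 nodes at branching 2 already reach depth 3).
#'
#' @param n_vaccine number of vaccine concepts (>= 1).
#' @param n_distractor number of non-vaccine concepts under a separate root.
#' @param branching children per node in the vaccine subtree.
#' @param seed integer seed; identical seeds give identical graphs.
#' @return a [concept_graph()].
#' @export
make_ontology <- function(n_vaccine = 100L, n_distractor = 20L,
                          branching = 3L, seed = 1L) {
  if (!is.numeric(n_vaccine) || n_vaccine < 1) {
    stop_("make_ontology(): n_vaccine must be >= 1")
  }
  if (n_distractor < 0 || branching < 1) {
    stop_("make_ontology(): invalid sizes")
  }
  set.seed(seed)
  categories <- c("conjugate vaccine", "inactivated vaccine",
                  "live attenuated vaccine", "subunit vaccine",
                  "toxoid vaccine", "recombinant vector vaccine",
                  "mrna vaccine", "polysaccharide vaccine")
  # up to two stems per vaccine node (label + brand synonym)
  stems <- make_stems(2L * n_vaccine + n_distractor + 8L)
  suffixes <- c("ix", "ax", "ol", "ek")

  id <- sprintf("VX:%07d", seq_len(n_vaccine))
  label <- character(n_vaccine)
  parents <- vector("list", n_vaccine)
  synonyms <- vector("list", n_vaccine)
  depth <- integer(n_vaccine)
  label[1] <- "vaccine"
  parents[[1]] <- character(0)
  synonyms[[1]] <- character(0)
  depth[1] <- 1L
  si <- 0L
  for (i in seq_len(n_vaccine)[-1]) {
    p <- ((i - 2L) %/% branching) + 1L
    parents[[i]] <- id[p]
    depth[i] <- depth[p] + 1L
    if (depth[i] == 2L) {
      label[i] <- categories[((i - 2L) %% length(categories)) + 1L]
    } else {
      si <- si + 1L
      label[i] <- paste(stems[si], label[p])
    }
    synonyms[[i]] <- if (depth[i] >= 3L) {
      si <- si + 1L
      paste0(cap1(stems[si]), suffixes[(i %% length(suffixes)) + 1L])
    } else {
      character(0)
    }
  }
  # second parents for a DAG: every 7th node of depth >= 3 also hangs off a
  # level-2 class node (never a descendant, so no cycle is possible)
  lvl2 <- which(depth == 2L)
  if (length(lvl2)) {
    for (i in seq_len(n_vaccine)) {
      if (depth[i] >= 3L && i %% 7L == 0L) {
        extra <- id[lvl2[(i %% length(lvl2)) + 1L]]
        parents[[i]] <- unique(c(parents[[i]], extra))
      }
    }
  }

  if (n_distractor > 0) {
    did <- sprintf("NX:%07d", seq_len(n_distractor))
    dlabel <- c("laboratory assay",
                paste(stems[n_vaccine + seq_len(n_distractor - 1)],
                      rep_len(c("assay", "antibody panel", "immunoglobulin"),
                              max(n_distractor - 1, 0))))
    dparents <- c(list(character(0)),
                  rep(list(did[1]), max(n_distractor - 1, 0)))
    id <- c(id, did)
    label <- c(label, dlabel[seq_len(n_distractor)])
    parents <- c(parents, dparents[seq_len(n_distractor)])
    synonyms <- c(synonyms, rep(list(character(0)), n_distractor))
  }

  concept_graph(data.frame(
    id = id, label = label,
    synonyms = I(synonyms), parents = I(parents),
    is_vaccine = c(rep(TRUE, n_vaccine),
                   rep(FALSE, length(id) - n_vaccine)),
    stringsAsFactors = FALSE
  ))
}

DOSE_TOKENS <- c("0.5 mL dose", "10 mcg", "Lot A1234", "2 doses", "50 ug")

#' Generate a noisy mention corpus with gold mappings
#'
#' Draws `n` mentions from the vaccine concepts of `graph` and perturbs them
#' under [noise_config()]. All random material is drawn up front in fixed
#' shape, so runs that differ only in the probability switches stay paired:
#' the same seed selects the same source concepts whatever noise is enabled.
#'
#' Noise semantics mirror how such mentions are annotated: a placebo suffix
#' maps to the vaccine itself; a product parenthetical uses the concept's
#' own brand synonym (same gold concept); a two-product mention lists both
#' gold ids; abbreviations replace the label with its initials; the OOV
#' fraction uses labels absent from the graph, with gold ids in a reserved
#' `OOV:` namespace.
#'
#' @param graph a [concept_graph()] with at least one vaccine concept.
#' @param n number of mentions.
#' @param cfg a [noise_config()]; its `seed` drives all randomness.
#' @return list with `mentions` (data.frame `mention_id`, `mention`) and
#'   `gold` (a [gold_standard()]).
#' @export
make_mentions <- function(graph, n, cfg = noise_config()) {
  stopifnot(inherits(graph, "concept_graph"), inherits(cfg, "noise_config"))
  co <- graph$concepts
  vax <- which(co$is_vaccine)
  if (!length(vax)) stop_("make_mentions(): graph has no vaccine concepts")
  set.seed(cfg$seed)
  # fixed-shape random material (branch gates consume nothing extra)
  primary <- sample(vax, n, replace = TRUE)
  secondary <- sample(vax, n, replace = TRUE)
  gates <- matrix(stats::runif(n * 7L), n, 7L,
                  dimnames = list(NULL, c("oov", "multi", "abbrev", "product",
                                          "misspell", "placebo", "dose")))
  u_pos <- stats::runif(n)
  dose_pick <- sample.int(length(DOSE_TOKENS), n, replace = TRUE)
  oov_stems <- make_stems(n)

  mention <- character(n)
  gold <- vector("list", n)
  n_oov <- 0L
  for (i in seq_len(n)) {
    if (gates[i, "oov"] < cfg$oov_rate) {
      n_oov <- n_oov + 1L
      base <- paste(cap1(oov_stems[i]), "experimental vaccine")
      gold[[i]] <- sprintf("OOV:%07d", n_oov)
    } else {
      pi <- primary[i]
      base <- cap1(co$label[pi])
      gold[[i]] <- co$id[pi]
      if (gates[i, "multi"] < cfg$p_multi_concept) {
        sj <- secondary[i]
        if (sj == pi) sj <- vax[(match(pi, vax) %% length(vax)) + 1L]
        base <- paste0(base, ", ", cap1(co$label[sj]))
        gold[[i]] <- unique(c(gold[[i]], co$id[sj]))
      } else if (gates[i, "abbrev"] < cfg$p_abbreviation) {
        base <- paste(toupper(substr(word_tokens(co$label[pi]), 1, 1)),
                      collapse = "")
      } else if (gates[i, "product"] < cfg$p_product_parenthetical &&
                 length(co$synonyms[[pi]])) {
        base <- paste0(base, " (", co$synonyms[[pi]][1], " ®)")
      }
    }
    if (gates[i, "misspell"] < cfg$p_misspell && nchar(base) >= 3) {
      p <- 1L + as.integer(floor(u_pos[i] * (nchar(base) - 2L)))
      base <- paste0(substr(base, 1, p - 1), substr(base, p + 1, p + 1),
                     substr(base, p, p), substr(base, p + 2, nchar(base)))
    }
    if (gates[i, "placebo"] < cfg$p_placebo_suffix) {
      base <- paste(base, "Placebo")
    }
    if (gates[i, "dose"] < cfg$p_dose_noise) {
      base <- paste(base, DOSE_TOKENS[dose_pick[i]])
    }
    mention[i] <- base
  }
  mention_id <- sprintf("m%05d", seq_len(n))
  list(
    mentions = data.frame(mention_id = mention_id, mention = mention,
                          stringsAsFactors = FALSE),
    gold = gold_standard(mention_id, mention, gold)
  )
}

#' Generate a registry-style interventions table
#'
#' Embeds each mention as a `'Biological'` row and pads the table with
#' background rows — drug/procedure/device interventions and biological
#' rows that are not vaccines — then shuffles row order. Deterministic per
#' seed.
#'
#' @param mentions data.frame with columns `mention_id`, `mention` (from
#'   [make_mentions()] or [build_corpus()]).
#' @param n_background number of distractor rows.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `nct_id`, `intervention_type`,
#'   `name`.
#' @export
make_interventions <- function(mentions, n_background = 300L, seed = 1L) {
  stopifnot(is.data.frame(mentions), nrow(mentions) >= 1)
  if (n_background < 0) stop_("make_interventions(): n_background < 0")
  set.seed(seed)
  n_m <- nrow(mentions)
  bg_types <- c("Drug", "Procedure", "Device", "Other",
                "Dietary Supplement", "Biological")
  bg_bio_names <- c("Placebo", "Normal saline", "Adjuvant alone",
                    "0.9% sodium chloride", "Immunoglobulin infusion")
  if (n_background > 0) {
    stems <- make_stems(n_background)
    types <- sample(bg_types, n_background, replace = TRUE,
                    prob = c(0.4, 0.15, 0.1, 0.1, 0.1, 0.15))
    names_bg <- ifelse(
      types == "Biological",
      sample(bg_bio_names, n_background, replace = TRUE),
      paste(cap1(stems), sample(c("tablet", "infusion", "capsule", "gel"),
                                n_background, replace = TRUE))
    )
  } else {
    types <- character(0)
    names_bg <- character(0)
  }
  tab <- data.frame(
    id = seq_len(n_m + n_background),
    nct_id = sprintf("NCT%08d",
                     sample.int(99999999L, n_m + n_background)),
    intervention_type = c(rep("Biological", n_m), types),
    name = c(mentions$mention, names_bg),
    stringsAsFactors = FALSE
  )
  tab <- tab[sample.int(nrow(tab)), , drop = FALSE]
  tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
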