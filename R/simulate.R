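#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's
#' RNG state, so simulators are bit-reproducible without disturbing the
#' session.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Substitution-only mutagenesis to a target identity
#'
#' Replaces `round((100 - target) / 100 * n)` uniformly drawn positions
#' with a different letter each, so the realized global identity equals
#' the target up to rounding (well within the +/- 5 point contract). No
#' indels are introduced; for protein-coding DNA no synonymous bias is
#' attempted (positions are uniform).
#'
#' @param sequence DNA or protein string.
#' @param target_identity Percent in \[20, 100\].
#' @param alphabet `"dna"` or `"protein"`.
#' @param seed Optional seed for deterministic output.
#' @return The mutated sequence (attribute `realized_identity` records the
#'   exact percent identity to the input).
#' @export
mutate_to_identity <- function(sequence, target_identity,
                               alphabet = c("dna", "protein"), seed = NULL) {
  alphabet <- match.arg(alphabet)
  stopifnot(target_identity >= 20, target_identity <= 100)
  run <- function() {
    letters_ <- if (alphabet == "dna") c("A", "C", "G", "T")
    else strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    v <- strsplit(sequence, "")[[1]]
    n <- length(v)
    k <- round((100 - target_identity) / 100 * n)
    if (k > 0) {
      idx <- sample.int(n, k)
      for (i in idx) {
        choices <- setdiff(letters_, v[i])
        v[i] <- choices[sample.int(length(choices), 1)]
      }
    }
    out <- paste(v, collapse = "")
    attr(out, "realized_identity") <- 100 * (n - k) / n
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Uniform-codon reverse translation under genetic code 11 (RNG must
# already be seeded by the caller).
reverse_translate <- function(protein) {
  gc_tab <- Biostrings::getGeneticCode("11")
  inv <- split(names(gc_tab), unname(gc_tab))
  inv <- inv[names(inv) != "*"]
  v <- strsplit(protein, "")[[1]]
  codons <- vapply(v, function(a) {
    cands <- if (a %in% names(inv)) inv[[a]] else unlist(inv, use.names = FALSE)
    cands[sample.int(length(cands), 1)]
  }, "", USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

#' Specification of one simulated transposition module
#'
#' Captures everything [simulate_transposon()] needs: the gene arrangement
#' as a configuration string, the target protein identity of each gene
#' versus its library exemplar, the res-site geometry and the spacing.
#' Defaults are the canonical arrangement studied throughout the package:
#' divergent TA pair upstream of colinear tnpR/tnpA with a three-subsite
#' res between the antitoxin and tnpR.
#'
#' @param configuration Configuration string (see [parse_config()]).
#' @param identities Target percent identity vs the exemplar, either one
#'   number for all genes or one per gene token, each in \[20, 100\].
#' @param toxin_family,antitoxin_family Exemplar families for T/A tokens.
#' @param subgroup Transposase exemplar subgroup for the tnpA token.
#' @param res_arm,res_loop Subsite inverted-repeat arm and loop lengths (bp).
#' @param res_gap Gap between consecutive subsites (bp).
#' @param crossover_offset 0-based offset of the crossover AT within
#'   subsite I, or `NULL` for the span center.
#' @param intergenic Intergenic gap length (bp).
#' @param res_pad Padding flanking the res block (bp).
#' @param plant_res Plant a canonical res site (requires a resolvase gene
#'   in the configuration).
#' @param truncate_toxin Introduce an internal stop codon at 40% of the
#'   toxin gene.
#' @param background_gc GC content of spacer/background DNA.
#' @param seed Mandatory integer seed.
#' @param id Record identifier.
#' @return A list of class `tn_simspec`.
#' @export
sim_spec <- function(configuration = "<T <A tnpR> tnpA>", identities = 100,
                     toxin_family = "ParE", antitoxin_family = "ParD",
                     subgroup = "Tn3000", res_arm = 12, res_loop = 6,
                     res_gap = 20, crossover_offset = NULL, intergenic = 60,
                     res_pad = 30, plant_res = TRUE, truncate_toxin = FALSE,
                     background_gc = 0.5, seed, id = "tn_sim") {
  if (missing(seed)) stop("sim_spec requires an explicit seed")
  stopifnot(all(identities >= 20), all(identities <= 100))
  cfg <- parse_config(configuration)
  genes <- cfg$names[cfg$names != "!res!"]
  if (length(identities) == 1) identities <- rep(identities, length(genes))
  if (length(identities) != length(genes))
    stop("identities must be length 1 or one per gene token")
  if (plant_res && !any(genes %in% c("tnpR", "tnpI", "tnpS")))
    stop("canonical res site requested but configuration has no resolvase")
  structure(list(configuration = cfg, identities = identities,
                 toxin_family = toxin_family,
                 antitoxin_family = antitoxin_family, subgroup = subgroup,
                 res_arm = res_arm, res_loop = res_loop, res_gap = res_gap,
                 crossover_offset = crossover_offset,
                 intergenic = intergenic, res_pad = res_pad,
                 plant_res = plant_res, truncate_toxin = truncate_toxin,
                 background_gc = background_gc, seed = as.integer(seed),
                 id = id),
            class = "tn_simspec")
}

.token_role <- c(T = "toxin", A = "antitoxin", X = "unknown",
                 tnpA = "transposase", tnpR = "resolvase_S",
                 tnpI = "resolvase_Y", tnpS = "resolvase_Y_het",
                 tnpT = "helper")

pick_exemplar <- function(lib, token, spec) {
  p <- lib$proteins
  cand <- switch(token,
    "T" = p[p$role == "toxin" & p$family == spec$toxin_family, ],
    "A" = p[p$role == "antitoxin" & p$family == spec$antitoxin_family, ],
    "tnpA" = p[p$role == "transposase" & p$subgroup == spec$subgroup, ],
    "tnpR" = p[p$role == "resolvase_S", ],
    "tnpI" = p[p$role == "resolvase_Y", ],
    "tnpS" = p[p$role == "resolvase_Y_het", ],
    "tnpT" = p[p$role == "helper", ],
    "X" = NULL)
  if (is.null(cand)) return(NULL)
  if (nrow(cand) == 0)
    stop("no library exemplar for token ", token)
  cand[order(cand$id), ][1, ]
}

# Build one res subsite: perfect inverted repeat; subsite I carries the
# crossover AT inside its loop (RNG already seeded).
make_subsite <- function(arm, loop, with_at = FALSE, at_offset = NULL) {
  left <- random_dna(arm)
  mid <- random_dna(loop)
  if (with_at) {
    span <- 2 * arm + loop
    at0 <- if (is.null(at_offset)) floor((span - 2) / 2) else at_offset
    if (at0 < arm || at0 + 2 > arm + loop)
      stop("crossover offset must fall inside the subsite loop")
    li <- at0 - arm                      # 0-based offset within the loop
    mid_v <- strsplit(mid, "")[[1]]
    mid_v[li + 1] <- "A"; mid_v[li + 2] <- "T"
    mid <- paste(mid_v, collapse = "")
    crossover_local <- at0
  } else crossover_local <- NA_integer_
  list(seq = paste0(left, mid, revcomp(left)), crossover_local = crossover_local)
}

#' Simulate one transposition module
#'
#' Gene proteins are exemplars mutated to the target identities and
#' reverse-translated with uniform codon choice; genes are laid out per
#' the configuration with the stated gaps; the res site is planted as
#' three perfect inverted-repeat subsites with subsite III adjacent to the
#' resolvase gene and the crossover AT embedded in subsite I; 38-bp
#' terminal inverted repeats cap both ends. Output is bit-reproducible
#' given the spec (which includes the seed).
#'
#' @param spec A [sim_spec()].
#' @param lib Reference library supplying the exemplars.
#' @return A list of class `tn_simulated`: `record` (a [seq_record()]
#'   whose features are the planted truth), `truth` (the feature table),
#'   `realized_identities` (named per gene token index).
#' @export
simulate_transposon <- function(spec, lib = load_reference_library()) {
  stopifnot(inherits(spec, "tn_simspec"))
  with_seed(spec$seed, {
    cfg <- spec$configuration
    gene_idx <- which(cfg$names != "!res!")
    genes <- cfg$names[gene_idx]
    strands <- cfg$strands[gene_idx]
    # synthesize gene DNA
    gene_dna <- character(length(genes))
    realized <- numeric(length(genes))
    for (g in seq_along(genes)) {
      ex <- pick_exemplar(lib, genes[g], spec)
      prot <- if (is.null(ex)) random_protein(90) else ex$aa_sequence
      target <- spec$identities[g]
      mut <- mutate_to_identity(prot, target, alphabet = "protein")
      mut_v <- strsplit(mut, "")[[1]]; mut_v[1] <- "M"
      mut <- paste(mut_v, collapse = "")
      realized[g] <- 100 * mean(strsplit(prot, "")[[1]] == mut_v)
      dna <- paste0(reverse_translate(mut), "TAA")
      if (spec$truncate_toxin && genes[g] == "T") {
        n_codon <- nchar(dna) / 3
        stop_at <- max(2, floor(0.4 * n_codon))
        substr(dna, 3 * (stop_at - 1) + 1, 3 * stop_at) <- "TAA"
      }
      gene_dna[g] <- if (strands[g] == "-") revcomp(dna) else dna
    }
    # decide the res slot: gap index (after gene i) on the resolvase 5' side,
    # or the explicit !res! position
    res_slot <- NA_integer_
    if (spec$plant_res) {
      res_tok <- which(cfg$names == "!res!")
      if (length(res_tok) == 1) {
        res_slot <- sum(cfg$names[seq_len(res_tok - 1)] != "!res!")
      } else {
        ri <- which(genes %in% c("tnpR", "tnpI", "tnpS"))[1]
        res_slot <- if (strands[ri] == "+") ri - 1L else ri
      }
    }
    # assemble left -> right
    parts <- character(); cursor <- 0L
    feats <- list(); realized_out <- c()
    push <- function(s) { parts[[length(parts) + 1]] <<- s; cursor <<- cursor + nchar(s) }
    feat <- function(type, start, end, strand, attrs = character()) {
      feats[[length(feats) + 1]] <<- list(type = type, start = start,
                                          end = end, strand = strand,
                                          attrs = attrs)
    }
    irl <- random_dna(38, spec$background_gc)
    push(irl)
    feat("terminal_IR", 0L, 38L, "+", c(side = "left"))
    resolvase_idx <- which(genes %in% c("tnpR", "tnpI", "tnpS"))[1]
    res_before_resolvase <- !is.na(res_slot) &&
      !is.na(resolvase_idx) && res_slot < resolvase_idx
    # res-block spacers use the complement-disjoint {A,C} alphabet: no
    # pairing between two spacer bases can ever complement, so the planted
    # subsites are provably the best-scoring inverted repeats in their
    # region and the recorded truth is the unique optimum
    random_ac <- function(n) paste(sample(c("A", "C"), n, replace = TRUE),
                                   collapse = "")
    emit_res <- function() {
      push(random_ac(spec$res_pad))
      region_start <- cursor
      # subsite III proximal to the resolvase
      order_labels <- if (res_before_resolvase) c("I", "II", "III")
      else c("III", "II", "I")
      for (j in seq_along(order_labels)) {
        lab <- order_labels[j]
        ss <- make_subsite(spec$res_arm, spec$res_loop,
                           with_at = lab == "I",
                           at_offset = spec$crossover_offset)
        s0 <- cursor
        push(ss$seq)
        feat(paste0("res_subsite_", lab), s0, cursor, "*",
             c(arm_len = as.character(spec$res_arm)))
        if (lab == "I") {
          cross <- s0 + ss$crossover_local
          feat("crossover_AT", cross, cross + 2L, "*", character())
        }
        if (j < length(order_labels))
          push(random_ac(spec$res_gap))
      }
      feat("res_site", region_start, cursor, "*", character())
      push(random_ac(spec$res_pad))
    }
    if (!is.na(res_slot) && res_slot == 0L) emit_res()
    for (g in seq_along(genes)) {
      s0 <- cursor
      push(gene_dna[g])
      role <- unname(.token_role[genes[g]])
      ex_fam <- switch(genes[g], "T" = spec$toxin_family,
                       "A" = spec$antitoxin_family, NA_character_)
      attrs <- c(token = genes[g],
                 target_identity = sprintf("%.1f", spec$identities[g]),
                 realized_identity = sprintf("%.2f", realized[g]))
      if (!is.na(ex_fam)) attrs <- c(attrs, family = ex_fam)
      if (spec$truncate_toxin && genes[g] == "T")
        attrs <- c(attrs, truncated = "true")
      feat(role, s0, cursor, strands[g], attrs)
      if (g < length(genes)) {
        if (!is.na(res_slot) && res_slot == g) emit_res()
        else push(random_dna(spec$intergenic, spec$background_gc))
      } else if (!is.na(res_slot) && res_slot == g) emit_res()
    }
    push(random_dna(10, spec$background_gc))
    irr_start <- cursor
    push(revcomp(irl))
    feat("terminal_IR", irr_start, irr_start + 38L, "+", c(side = "right"))
    seq <- paste(parts, collapse = "")
    ft <- feature_table(
      seq_id = rep(spec$id, length(feats)),
      start = vapply(feats, function(f) as.numeric(f$start), 0),
      end = vapply(feats, function(f) as.numeric(f$end), 0),
      strand = vapply(feats, `[[`, "", "strand"),
      feature_type = vapply(feats, `[[`, "", "type"),
      attributes = lapply(feats, `[[`, "attrs"))
    rec <- seq_record(spec$id, seq, source_format = "fasta", features = ft)
    structure(list(record = rec, truth = ft,
                   realized_identities = setNames(realized, genes),
                   spec = spec),
              class = "tn_simulated")
  })
}

#' Simulate a genome with embedded modules
#'
#' Plants each simulated module at a random position in a random
#' background of the stated GC, keeping at least 3 kb between modules (and
#' to the sequence ends), and shifts the truth coordinates accordingly.
#'
#' @param specs A list of [sim_spec()]s (possibly empty for a pure
#'   background genome).
#' @param background_length Background length in bp.
#' @param gc Background GC fraction.
#' @param seed Integer seed.
#' @param lib Reference library.
#' @param id Record identifier.
#' @return A `tn_simulated` list: `record` (with truth features),
#'   `truth`, `modules` (per-module `tn_simulated` objects).
#' @export
simulate_genome <- function(specs, background_length = 50000, gc = 0.5,
                            seed, lib = load_reference_library(),
                            id = "genome_sim") {
  stopifnot(!missing(seed))
  mods <- lapply(specs, simulate_transposon, lib = lib)
  with_seed(child_seed(seed, 777L), {
    k <- length(mods)
    bg <- random_dna(background_length, gc)
    if (k == 0) {
      rec <- seq_record(id, bg, source_format = "fasta")
      return(structure(list(record = rec, truth = feature_table(),
                            modules = list()), class = "tn_simulated"))
    }
    sep <- 3000
    ok <- FALSE
    for (try in seq_len(200)) {
      pos <- sort(sample.int(background_length - 1, k))
      if (k == 1 || min(diff(pos)) >= sep) { ok <- TRUE; break }
    }
    if (!ok) stop("insufficient space to place modules >= 3 kb apart")
    parts <- character(); feats <- feature_table(); cursor <- 0L; prev <- 0L
    for (i in seq_len(k)) {
      parts <- c(parts, substr(bg, prev + 1, pos[i]))
      cursor <- cursor + (pos[i] - prev)
      ft <- mods[[i]]$truth
      ft$start <- ft$start + cursor; ft$end <- ft$end + cursor
      ft$seq_id <- id
      feats <- rbind(feats, ft)
      parts <- c(parts, mods[[i]]$record$sequence)
      cursor <- cursor + nchar(mods[[i]]$record$sequence)
      prev <- pos[i]
    }
    parts <- c(parts, substr(bg, prev + 1, background_length))
    seq <- paste(parts, collapse = "")
    class(feats) <- c("tn_features", "data.frame")
    rec <- seq_record(id, seq, source_format = "fasta", features = feats)
    structure(list(record = rec, truth = feats, modules = mods),
              class = "tn_simulated")
  })
}

#' Join two simulated transposons at res site I (or a custom position)
#'
#' Models intertransposon recombination: the chimera is the left part of
#' parent A up to (and including) the A of its crossover AT dinucleotide,
#' followed by the right part of parent B from the T of its crossover
#' onward. The junction position (on chimera = parent A coordinates) is
#' recorded in the truth.
#'
#' @param tnA,tnB `tn_simulated` parents (both need planted crossovers for
#'   the res-site junction mode).
#' @param junction `"res_site_I_crossover"` or an integer position `j`
#'   (1-based: chimera = A\[1..j\] + B\[j+1..\]).
#' @param id Chimera record id.
#' @return A `tn_simulated` list with `junction` (1-based last A-derived
#'   position) in the truth attributes.
#' @export
simulate_chimera <- function(tnA, tnB, junction = "res_site_I_crossover",
                             id = "tn_chimera") {
  get_cross <- function(tn) {
    ft <- tn$truth
    i <- which(ft$feature_type == "crossover_AT")
    if (length(i) == 0) stop("parent lacks a planted crossover AT")
    ft$start[i[1]]
  }
  if (identical(junction, "res_site_I_crossover")) {
    pA <- get_cross(tnA); pB <- get_cross(tnB)
    cutA <- pA + 1L          # 1-based: keep A[1..pA+1] (through the 'A')
    cutB <- pB + 1L
  } else {
    cutA <- cutB <- as.integer(junction)
  }
  sa <- tnA$record$sequence; sb <- tnB$record$sequence
  if (cutA < 1 || cutA >= nchar(sa) || cutB < 1 || cutB >= nchar(sb))
    stop("junction outside parent sequences")
  seq <- paste0(substr(sa, 1, cutA), substr(sb, cutB + 1, nchar(sb)))
  shift <- cutA - cutB
  fa <- tnA$truth[tnA$truth$end <= cutA, , drop = FALSE]
  fb <- tnB$truth[tnB$truth$start >= cutB, , drop = FALSE]
  if (nrow(fb) > 0) { fb$start <- fb$start + shift; fb$end <- fb$end + shift }
  ft <- rbind(fa, fb)
  if (nrow(ft) > 0) ft$seq_id <- id
  class(ft) <- c("tn_features", "data.frame")
  rec <- seq_record(id, seq, source_format = "fasta", features = ft)
  out <- structure(list(record = rec, truth = ft, junction = cutA),
                   class = "tn_simulated")
  out
}

#' Derive a diverged copy of a simulated sequence
#'
#' Substitution-only mutation of a simulated record to a target DNA
#' identity. Because no indels are introduced, every planted feature keeps
#' its coordinates, so the copy serves as a diverged parent with the same
#' truth layout (e.g. the second parent of a chimera).
#'
#' @param tn A `tn_simulated`.
#' @param identity Target percent DNA identity to the original.
#' @param seed Integer seed.
#' @param id New record id.
#' @return A `tn_simulated` with mutated sequence and shifted-id truth.
#' @export
mutate_simulated <- function(tn, identity, seed, id = paste0(tn$record$id, "_div")) {
  seq <- mutate_to_identity(tn$record$sequence, identity, alphabet = "dna",
                            seed = seed)
  ft <- tn$truth
  if (nrow(ft) > 0) ft$seq_id <- id
  class(ft) <- c("tn_features", "data.frame")
  rec <- seq_record(id, as.character(seq), source_format = "fasta",
                    features = ft)
  structure(list(record = rec, truth = ft,
                 realized_identity = attr(seq, "realized_identity")),
            class = "tn_simulated")
}

#' Build a locus from planted truth features
#'
#' Converts the gene features of a simulated record into a `tn_locus`, as
#' if every planted gene had been recovered perfectly — used to exercise
#' res-site scanning and adjacency annotation independently of the
#' homology screen.
#'
#' @param tn A `tn_simulated`.
#' @return A `tn_locus` (members carry pseudo-alignment fields).
#' @export
truth_locus <- function(tn) {
  ft <- tn$truth
  roles <- c("toxin", "antitoxin", "transposase", "resolvase_S",
             "resolvase_Y", "resolvase_Y_het", "helper", "unknown")
  g <- ft[ft$feature_type %in% roles, , drop = FALSE]
  if (nrow(g) == 0) stop("no gene features in truth")
  m <- data.frame(seq_id = g$seq_id, start = g$start, end = g$end,
                  strand = g$strand, frame = 0L, partial = FALSE,
                  aa_len = (g$end - g$start) %/% 3L - 1L,
                  aa_sequence = NA_character_, ref_id = "truth",
                  role = g$feature_type, family = NA_character_,
                  superfamily = NA_character_, subgroup = NA_character_,
                  score = 1000, identity = 100, coverage = 100,
                  q_start = NA_integer_, q_end = NA_integer_,
                  r_start = NA_integer_, r_end = NA_integer_,
                  ref_len = NA_integer_, stringsAsFactors = FALSE)
  m <- m[order(m$start), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("tn_hits", "data.frame")
  structure(list(seq_id = m$seq_id[1], start = min(m$start),
                 end = max(m$end), members = m, configuration = NULL,
                 completeness = NA_character_, missing_roles = character(),
                 subgroup = NA_character_, resolvase_type = "none",
                 ta_order = NA_character_, notes = character()),
            class = "tn_locus")
}

#' Simulate toxin sets with a known number of independent origins
#'
#' Draws `k` mutually unrelated ancestor proteins, each spawning
#' `n_per_origin` transposon-associated descendants within `divergence`
#' p-distance of the ancestor, plus `n_seeds` seed-origin sequences
#' interleaved between the origin clusters: seeds are placed at about 1.5
#' times the divergence from the ancestors (cycling over them), so each
#' origin cluster is separated from its neighbors by a seed taxon in the
#' tree — emulating reference family members that are not
#' transposon-borne.
#'
#' @param k Number of independent origins (>= 1).
#' @param n_per_origin Descendants per origin.
#' @param divergence Maximum within-origin p-distance (fraction).
#' @param n_seeds Number of seed sequences (default `k + 2`).
#' @param seed Integer seed.
#' @param aa_len Protein length.
#' @return A `tn_toxinset` with origins labeled.
#' @export
simulate_toxin_origins <- function(k, n_per_origin = 3, divergence = 0.1,
                                   n_seeds = k + 2, seed, aa_len = 100) {
  stopifnot(k >= 1, !missing(seed))
  with_seed(seed, {
    ancestors <- replicate(k, random_protein(aa_len))
    ids <- c(); seqs <- c(); origins <- c()
    for (i in seq_len(k)) {
      # cluster founder: the shared derived branch that makes each origin
      # a recoverable clade (descendants inherit its substitutions)
      founder <- mutate_to_identity(ancestors[i],
                                    100 * (1 - 0.6 * divergence),
                                    alphabet = "protein")
      for (j in seq_len(n_per_origin)) {
        d <- 0.4 * divergence * runif(1, 0.5, 1)
        seqs <- c(seqs, mutate_to_identity(founder, 100 * (1 - d),
                                           alphabet = "protein"))
        ids <- c(ids, sprintf("tn_o%d_%d", i, j))
        origins <- c(origins, "tn_associated")
      }
    }
    for (s in seq_len(n_seeds)) {
      anc <- ancestors[((s - 1) %% k) + 1]
      d <- min(0.8, 1.5 * divergence)
      seqs <- c(seqs, mutate_to_identity(anc, 100 * (1 - d),
                                         alphabet = "protein"))
      ids <- c(ids, sprintf("seed_%d", s))
      origins <- c(origins, "seed")
    }
    toxin_set(ids, seqs, origins, family = "simulated")
  })
}
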