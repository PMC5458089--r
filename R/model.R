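# Network definition: species table, reaction table, stoichiometric matrix.
# The shipped CSVs under inst/extdata define the full 23-reaction network;
# build_full_system() assembles them into a validated tf_model.

# parse "2 AcCoA + ATP -> IPP + ADP" into named coefficient vectors
parse_equation <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L)
    stop("equation must contain exactly one '->': ", eq, call. = FALSE)
  parse_side <- function(side) {
    terms <- strsplit(side, "+", fixed = TRUE)[[1]]
    terms <- trimws(terms)
    terms <- terms[nzchar(terms)]
    coef <- integer(0)
    for (tm in terms) {
      parts <- strsplit(tm, "[[:space:]]+")[[1]]
      if (length(parts) == 1L) {
        n <- 1L; sp <- parts
      } else if (length(parts) == 2L && grepl("^[0-9]+$", parts[1])) {
        n <- as.integer(parts[1]); sp <- parts[2]
      } else {
        stop("cannot parse term '", tm, "' in equation: ", eq, call. = FALSE)
      }
      coef[sp] <- (if (sp %in% names(coef)) coef[[sp]] else 0L) + n
    }
    coef
  }
  list(substrates = parse_side(sides[1]), products = parse_side(sides[2]))
}

# parse "Glc=0.12;ATP=0.2" into a named numeric vector
parse_km <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric(0))
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- vapply(kv, function(x) as.numeric(x[2]), 0)
  names(out) <- vapply(kv, function(x) trimws(x[1]), "")
  out
}

.synthase_catalysts <- c(limonene = "LimoneneSynthase",
                         pinene = "PineneSynthase",
                         sabinene = "SabineneSynthase")

# roster entries with no kinetic reaction: the three pyruvate-dehydrogenase
# subunits replace the lumped Pdh entry, and catalase plus glutathione
# reductase are present in the reaction mix purely as a redox safeguard
.PDH_SUBUNITS <- c("AceE", "AceF", "Lpd")
.ROSTER_ONLY <- c("Catalase", "GlutathioneReductase")

#' Assemble the full glucose-to-monoterpene model
#'
#' Builds the complete 23-reaction network (glycolysis with the Gap/mGap/NoxE
#' purge valve, pyruvate dehydrogenase, the mevalonate pathway, prenyl
#' assembly, a swappable terpene synthase and pyrophosphatase) from the
#' shipped species/reaction/initial-state tables. The initial state is the
#' continuous-production recipe (20 mM Pi, 1 mM FBP primer, 4 mM ATP, 1.5 mM
#' NADP+, 0.2 mM NAD+, 1.5 mM CoA) with the glucose load as an argument.
#'
#' @param synthase Which terpene synthase closes the pathway; the product is a
#'   C10H16 isomer (MW 136.24 g/mol) in every case, so swapping the synthase
#'   changes only the final reaction's identity.
#' @param glucose_mM Initial glucose concentration (mM).
#' @param vmax Optional named numeric vector of enzyme-loading overrides
#'   (U ml^-1), keyed by catalyst name (use the synthase's catalyst name or
#'   `"TerpeneSynthase"` for the synthase).
#' @param init Optional named numeric vector of initial-concentration
#'   overrides (mM), keyed by species id.
#' @param species_file,reactions_file,init_file Paths to the model-definition
#'   tables; defaults are the shipped files.
#' @return A `tf_model`: species table, reaction table, rate laws,
#'   stoichiometric matrix, initial state and metadata.
#' @export
build_full_system <- function(synthase = c("limonene", "pinene", "sabinene"),
                              glucose_mM = 500,
                              vmax = NULL, init = NULL,
                              species_file = tf_extdata("species.csv"),
                              reactions_file = tf_extdata("reactions.csv"),
                              init_file = tf_extdata("initial_state_continuous.csv")) {
  synthase <- match.arg(synthase)
  species <- utils::read.csv(species_file, stringsAsFactors = FALSE)
  reactions <- utils::read.csv(reactions_file, stringsAsFactors = FALSE)
  init_tab <- utils::read.csv(init_file, stringsAsFactors = FALSE)

  # synthase swap: only the final reaction's id/catalyst change
  ts <- reactions$catalyst == "TerpeneSynthase"
  if (sum(ts) != 1L)
    stop("model definition must contain exactly one terpene synthase reaction",
         call. = FALSE)
  reactions$id[ts] <- paste0(synthase, "_synthase")
  reactions$catalyst[ts] <- .synthase_catalysts[[synthase]]

  if (anyDuplicated(species$id))
    stop("duplicate species id in ", species_file, call. = FALSE)
  if (anyDuplicated(reactions$id))
    stop("duplicate reaction id in ", reactions_file, call. = FALSE)

  ns <- nrow(species); nr <- nrow(reactions)
  S <- matrix(0, ns, nr, dimnames = list(species$id, reactions$id))
  laws <- vector("list", nr); names(laws) <- reactions$id
  for (i in seq_len(nr)) {
    eq <- parse_equation(reactions$equation[i])
    unknown <- setdiff(c(names(eq$substrates), names(eq$products)), species$id)
    if (length(unknown))
      stop("reaction ", reactions$id[i], " uses unknown species: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    S[names(eq$substrates), i] <- S[names(eq$substrates), i] - eq$substrates
    S[names(eq$products), i] <- S[names(eq$products), i] + eq$products
    km <- parse_km(reactions$km[i])
    if (is.na(reactions$vmax_U_per_ml[i]))
      stop("missing Vmax for reaction ", reactions$id[i], call. = FALSE)
    laws[[i]] <- rate_law(
      form = reactions$rate_law[i],
      vmax = reactions$vmax_U_per_ml[i],
      km = km,
      keq = suppressWarnings(as.numeric(reactions$keq[i])),
      substrates = eq$substrates,
      products = eq$products
    )
  }

  init0 <- stats::setNames(numeric(ns), species$id)
  init0[init_tab$species] <- init_tab$concentration_mM
  init0["Glc"] <- glucose_mM

  model <- structure(
    list(species = species, reactions = reactions, stoich = S, rate_laws = laws,
         init = init0,
         metadata = list(synthase = synthase,
                         product_species = "Terpene",
                         product_mw = MONOTERPENE_MW)),
    class = "tf_model"
  )
  if (!is.null(vmax)) for (cz in names(vmax)) model <- set_vmax(model, cz, vmax[[cz]])
  if (!is.null(init)) for (sp in names(init)) model <- set_initial(model, sp, init[[sp]])
  model
}

# path helper that also works from a source checkout (tests, scripts)
tf_extdata <- function(file) {
  p <- system.file("extdata", file, package = "terpflux")
  if (nzchar(p)) return(p)
  local <- file.path("inst", "extdata", file)
  if (file.exists(local)) return(local)
  stop("cannot locate model definition file ", file, call. = FALSE)
}

#' Stoichiometric matrix of a model
#' @param model A `tf_model`.
#' @return Species-by-reaction integer matrix.
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  model$stoich
}

#' Override an enzyme loading
#' @param model A `tf_model`.
#' @param catalyst Catalyst name (`"TerpeneSynthase"` matches whichever
#'   synthase is installed).
#' @param vmax_U_per_ml New loading (U ml^-1); 0 is a knockout.
#' @export
set_vmax <- function(model, catalyst, vmax_U_per_ml) {
  stopifnot(inherits(model, "tf_model"))
  idx <- which(model$reactions$catalyst == catalyst)
  if (!length(idx) && catalyst == "TerpeneSynthase")
    idx <- which(model$reactions$catalyst %in% .synthase_catalysts)
  if (!length(idx))
    stop("unknown catalyst: ", catalyst, call. = FALSE)
  if (vmax_U_per_ml < 0) stop("Vmax must be non-negative", call. = FALSE)
  for (i in idx) {
    model$reactions$vmax_U_per_ml[i] <- vmax_U_per_ml
    model$rate_laws[[i]]$vmax <- vmax_U_per_ml
  }
  model$compiled <- NULL
  model
}

#' Override an initial concentration
#' @param model A `tf_model`.
#' @param species Species id.
#' @param mM New initial concentration (mM, non-negative).
#' @export
set_initial <- function(model, species, mM) {
  stopifnot(inherits(model, "tf_model"))
  if (!species %in% model$species$id)
    stop("unknown species: ", species, call. = FALSE)
  if (mM < 0) stop("concentrations must be non-negative", call. = FALSE)
  model$init[[species]] <- mM
  model
}

#' Get an enzyme loading
#' @inheritParams set_vmax
#' @return Loading in U ml^-1.
#' @export
get_vmax <- function(model, catalyst) {
  idx <- which(model$reactions$catalyst == catalyst)
  if (!length(idx) && catalyst == "TerpeneSynthase")
    idx <- which(model$reactions$catalyst %in% .synthase_catalysts)
  if (!length(idx)) stop("unknown catalyst: ", catalyst, call. = FALSE)
  model$reactions$vmax_U_per_ml[idx[1]]
}

#' Enumerate the protein catalysts of the assembled system
#'
#' The lumped pyruvate-dehydrogenase reaction is carried out by a three-subunit
#' complex (AceE, AceF, Lpd), and catalase plus glutathione reductase are part
#' of the reaction mix (redox safeguard) without a kinetic reaction, so the
#' full system counts 27 distinct protein catalysts over its 23 kinetic
#' reactions.
#'
#' @param model A `tf_model`.
#' @return Character vector of catalyst names.
#' @export
catalyst_roster <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  kin <- model$reactions$catalyst
  roster <- unlist(lapply(kin, function(cz)
    if (cz == "Pdh") .PDH_SUBUNITS else cz), use.names = FALSE)
  c(roster, .ROSTER_ONLY)
}

#' Conserved-moiety vectors of the network
#'
#' Returns the five structural conservation relations: adenine (ATP + ADP),
#' nicotinamide-NAD (NAD+ + NADH), nicotinamide-NADP (NADP+ + NADPH),
#' coenzyme A (free CoA and all thioesters) and total transferable phosphate
#' (Pi + 2 PPi + 3 ATP + 2 ADP + all phosphorylated intermediates; the
#' structural 2'-phosphate of NADP is excluded because it is never
#' transferred). Each vector v satisfies t(v) %*% S == 0.
#'
#' @param model A `tf_model`.
#' @param check If TRUE (default), verify each vector annihilates the
#'   stoichiometric matrix and report the violating reaction otherwise.
#' @return Named list of named numeric vectors over all species.
#' @export
conserved_moieties <- function(model, check = TRUE) {
  stopifnot(inherits(model, "tf_model"))
  cols <- c(adenine = "adenine", NAD = "nicotinamide_nad",
            NADP = "nicotinamide_nadp", CoA = "coenzyme_a",
            total_phosphate = "phosphate")
  S <- model$stoich
  out <- lapply(cols, function(cl)
    stats::setNames(as.numeric(model$species[[cl]]), model$species$id))
  if (check) {
    for (nm in names(out)) {
      resid <- as.vector(out[[nm]] %*% S)
      bad <- which(abs(resid) > 1e-9)
      if (length(bad))
        stop("moiety '", nm, "' is not conserved; violating reaction(s): ",
             paste(colnames(S)[bad], collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Validate a model definition
#'
#' Diagnostic pass over the network: per-reaction carbon balance, per-reaction
#' balance of each moiety (adenine, NAD, NADP, CoA, transferable phosphate),
#' duplicate ids, orphan species, non-integer stoichiometry and synthase
#' multiplicity. The shipped model yields an empty report.
#'
#' @param model A `tf_model`.
#' @return Data frame with columns `type`, `where`, `detail`; zero rows when
#'   the model is clean.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "tf_model"))
  S <- model$stoich
  sp <- model$species
  issues <- list()
  add <- function(type, where, detail)
    issues[[length(issues) + 1L]] <<- data.frame(type = type, where = where,
                                                 detail = detail)

  balances <- list(carbon = "carbon", adenine = "adenine",
                   NAD = "nicotinamide_nad", NADP = "nicotinamide_nadp",
                   CoA = "coenzyme_a", phosphate = "phosphate")
  for (nm in names(balances)) {
    w <- stats::setNames(as.numeric(sp[[balances[[nm]]]]), sp$id)
    resid <- as.vector(w %*% S)
    for (j in which(abs(resid) > 1e-9))
      add(paste0(nm, "_imbalance"), colnames(S)[j],
          sprintf("net %s change %+g", nm, resid[j]))
  }
  if (any(S != round(S)))
    add("non_integer_stoichiometry",
        paste(colnames(S)[colSums(S != round(S)) > 0], collapse = ","), "")
  if (anyDuplicated(model$reactions$id))
    add("duplicate_reaction_id",
        paste(unique(model$reactions$id[duplicated(model$reactions$id)]),
              collapse = ","), "")
  if (anyDuplicated(sp$id))
    add("duplicate_species_id",
        paste(unique(sp$id[duplicated(sp$id)]), collapse = ","), "")
  orphan <- rownames(S)[rowSums(abs(S)) == 0]
  for (o in orphan) add("orphan_species", o, "appears in no reaction")
  n_ts <- sum(model$reactions$catalyst %in%
                c(.synthase_catalysts, "TerpeneSynthase"))
  if (n_ts != 1L)
    add("synthase_count", "model", sprintf("%d synthase reactions", n_ts))
  if (any(model$init < 0))
    add("negative_initial", paste(names(model$init)[model$init < 0],
                                  collapse = ","), "")
  if (length(issues)) do.call(rbind, issues)
  else data.frame(type = character(), where = character(), detail = character())
}

#' Extract a submodel containing a subset of reactions
#'
#' Species are retained (rows of unused species become zero), so conservation
#' analyses on submodules stay aligned with the full model.
#'
#' @param model A `tf_model`.
#' @param reaction_ids Character vector of reaction ids to keep.
#' @return A `tf_model` with the reduced reaction set.
#' @export
subset_model <- function(model, reaction_ids) {
  stopifnot(inherits(model, "tf_model"))
  missing <- setdiff(reaction_ids, model$reactions$id)
  if (length(missing))
    stop("unknown reaction id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  keep <- model$reactions$id %in% reaction_ids
  model$reactions <- model$reactions[keep, , drop = FALSE]
  model$stoich <- model$stoich[, keep, drop = FALSE]
  model$rate_laws <- model$rate_laws[keep]
  model$compiled <- NULL
  model
}

#' Convenience submodules of the shipped network
#'
#' `mevalonate_module()` keeps the six reactions from thiolase through
#' diphosphomevalonate decarboxylase (PhaA, Hmgs, Hmgr, Mvk, Pmvk, Mdc), i.e.
#' acetyl-CoA in, IPP out. `glycolysis_module()` keeps hexokinase through
#' pyruvate kinase with the NAD-dependent Gap only, optionally adding the
#' lumped pyruvate dehydrogenase.
#'
#' @param model A full `tf_model`.
#' @param include_pdh Include the pyruvate-dehydrogenase reaction.
#' @return A `tf_model` restricted to the submodule.
#' @export
mevalonate_module <- function(model) {
  subset_model(model, c("PhaA", "Hmgs", "Hmgr", "Mvk", "Pmvk", "Mdc"))
}

#' @rdname mevalonate_module
#' @export
glycolysis_module <- function(model, include_pdh = FALSE) {
  ids <- c("Hex", "Pgi", "Pfk", "Fba", "Tpi", "Gap", "Pgk", "Pgm", "Eno", "Pyk")
  if (include_pdh) ids <- c(ids, "Pdh")
  subset_model(model, ids)
}

#' @export
print.tf_model <- function(x, ...) {
  cat("<tf_model> glucose-to-", x$metadata$synthase, " system\n", sep = "")
  cat("  ", nrow(x$reactions), "kinetic reactions,",
      nrow(x$species), "species,",
      length(catalyst_roster(x)), "catalysts in the roster\n")
  cat("  initial glucose:", x$init[["Glc"]], "mM\n")
  invisible(x)
}
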