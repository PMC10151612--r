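#' Load a metabolic model from disk
#'
#' Two dialects are supported: `"toy_tsv"`, a sectioned tab-separated format
#' for hand-written fixtures with exact coefficients, and `"sbml_fbc"`, SBML
#' Level 3 with the flux-bounds/objective (fbc) extension. Both yield a raw
#' model: exchange reactions are flagged but not yet externalized (see
#' [externalize_environment()]).
#'
#' The toy TSV dialect has five sections introduced by bracketed headers:
#' \preformatted{
#' # model <id> <collection>
#' [compounds]   base_id <TAB> compartment
#' [reactions]   reaction_id <TAB> base_id[compartment] <TAB> coefficient
#' [bounds]      reaction_id <TAB> lb <TAB> ub
#' [environment] base_id <TAB> lower <TAB> upper
#' [biomass]     reaction_id
#' }
#' Each `[environment]` line materializes an exchange reaction
#' `EX_<base_id>` with coefficient -1 on `base_id[e]` and the stated bounds.
#'
#' @param path file path.
#' @param dialect `"toy_tsv"` or `"sbml_fbc"` (default guessed from the
#'   extension: `.xml`/`.sbml` means SBML).
#' @return A raw `metabolic_model`.
#' @export
load_model <- function(path, dialect = NULL) {
  if (is.null(dialect))
    dialect <- if (grepl("\\.(xml|sbml)$", path)) "sbml_fbc" else "toy_tsv"
  dialect <- match.arg(dialect, c("toy_tsv", "sbml_fbc"))
  if (!file.exists(path)) stop("cannot read model file: ", path)
  switch(dialect, toy_tsv = .read_toy_tsv(path), sbml_fbc = .read_sbml(path))
}

#' Write a metabolic model to disk
#'
#' @param model a raw `metabolic_model` (exchange reactions present).
#' @param path output path.
#' @param dialect `"toy_tsv"` or `"sbml_fbc"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("toy_tsv", "sbml_fbc")) {
  dialect <- match.arg(dialect)
  switch(dialect, toy_tsv = .write_toy_tsv(model, path),
         sbml_fbc = .write_sbml(model, path))
  invisible(path)
}

.read_toy_tsv <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^# *model", lines, value = TRUE)
  if (length(hdr) != 1) stop("toy TSV must start with '# model <id> <collection>'")
  hp <- strsplit(sub("^# *model +", "", hdr), "[ \t]+")[[1]]
  id <- hp[1]; collection <- if (length(hp) >= 2) hp[2] else "default"
  lines <- lines[!grepl("^#", lines)]
  sec <- cumsum(grepl("^\\[", lines))
  names <- sub("^\\[(.*)\\]$", "\\1", lines[grepl("^\\[", lines)])
  parts <- split(lines[!grepl("^\\[", lines)],
                 factor(sec[!grepl("^\\[", lines)], levels = seq_along(names),
                        labels = names))
  fld <- function(section, n) {
    rows <- parts[[section]]
    if (is.null(rows) || !length(rows))
      return(matrix(character(0), 0, n))
    m <- do.call(rbind, strsplit(rows, "\t"))
    if (ncol(m) != n) stop("section [", section, "] expects ", n, " columns")
    m
  }
  cpd <- fld("compounds", 2)
  compounds <- data.frame(base_id = cpd[, 1], compartment = cpd[, 2],
                          stringsAsFactors = FALSE)
  trip <- fld("reactions", 3)
  bnds <- fld("bounds", 3)
  env <- fld("environment", 3)
  bio <- parts[["biomass"]]
  if (is.null(bio) || length(bio) != 1)
    stop("toy TSV must declare exactly one [biomass] reaction")
  rxn_ids <- unique(trip[, 1])
  keys <- cpd_key(compounds$base_id, compounds$compartment)
  ri <- match(trip[, 2], keys)
  if (anyNA(ri)) stop("reaction references unknown compound: ",
                      paste(unique(trip[is.na(ri), 2]), collapse = ", "))
  S <- Matrix::sparseMatrix(i = ri, j = match(trip[, 1], rxn_ids),
                            x = as.numeric(trip[, 3]),
                            dims = c(length(keys), length(rxn_ids)))
  lb <- setNames(rep(0, length(rxn_ids)), rxn_ids)
  ub <- setNames(rep(1000, length(rxn_ids)), rxn_ids)
  if (nrow(bnds)) {
    bi <- match(bnds[, 1], rxn_ids)
    if (anyNA(bi)) stop("bounds for unknown reaction")
    lb[bi] <- as.numeric(bnds[, 2]); ub[bi] <- as.numeric(bnds[, 3])
  }
  if (!(bio %in% rxn_ids)) stop("biomass reaction not found: ", bio)
  reactions <- data.frame(id = rxn_ids, lb = as.numeric(lb),
                          ub = as.numeric(ub), is_biomass = rxn_ids == bio,
                          is_exchange = FALSE, stringsAsFactors = FALSE)
  # environment lines materialize exchange reactions on base_id[e]
  if (nrow(env)) {
    ei <- match(cpd_key(env[, 1], "e"), keys)
    if (anyNA(ei)) stop("environment references unknown extracellular compound")
    Sx <- Matrix::sparseMatrix(i = ei, j = seq_len(nrow(env)), x = -1,
                               dims = c(length(keys), nrow(env)))
    S <- cbind(S, Sx)
    reactions <- rbind(reactions, data.frame(
      id = paste0("EX_", env[, 1]), lb = as.numeric(env[, 2]),
      ub = as.numeric(env[, 3]), is_biomass = FALSE, is_exchange = TRUE,
      stringsAsFactors = FALSE))
  }
  metabolic_model(id, compounds, reactions, S, collection = collection)
}

.write_toy_tsv <- function(model, path) {
  if (model$externalized)
    stop("toy TSV stores raw models; write before externalizing")
  out <- c(paste("# model", model$id, model$collection), "[compounds]")
  out <- c(out, paste(model$compounds$base_id, model$compounds$compartment,
                      sep = "\t"))
  out <- c(out, "[reactions]")
  Tm <- as(model$S, "TsparseMatrix")
  core <- !model$reactions$is_exchange
  for (k in which(core)) {
    sel <- Tm@j + 1L == k
    out <- c(out, paste(model$reactions$id[k],
                        model$compounds$key[Tm@i[sel] + 1L],
                        format(Tm@x[sel], digits = 15, trim = TRUE),
                        sep = "\t"))
  }
  out <- c(out, "[bounds]",
           paste(model$reactions$id[core],
                 format(model$reactions$lb[core], digits = 15, trim = TRUE),
                 format(model$reactions$ub[core], digits = 15, trim = TRUE),
                 sep = "\t"))
  ex <- which(model$reactions$is_exchange)
  envl <- character(0)
  for (k in ex) {
    nz <- which(model$S[, k] != 0)
    coef <- model$S[nz, k]
    l <- model$reactions$lb[k]; u <- model$reactions$ub[k]
    if (coef > 0) { tmp <- l; l <- -u; u <- -tmp }
    envl <- c(envl, paste(model$compounds$base_id[nz],
                          format(l, digits = 15, trim = TRUE),
                          format(u, digits = 15, trim = TRUE), sep = "\t"))
  }
  out <- c(out, "[environment]", envl, "[biomass]",
           model$reactions$id[model$biomass])
  writeLines(out, path)
}

# --- minimal SBML Level 3 + fbc ------------------------------------------

.sbml_ns <- c(s = "http://www.sbml.org/sbml/level3/version1/core",
              fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2")

.read_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path), error = function(e)
    stop("unreadable SBML file: ", conditionMessage(e)))
  ns <- .sbml_ns
  mod <- xml2::xml_find_first(doc, ".//s:model", ns)
  if (is.na(xml2::xml_attr(mod, "id"))) stop("SBML model without id")
  id <- xml2::xml_attr(mod, "id")
  collection <- xml2::xml_attr(mod, "name")
  if (is.na(collection)) collection <- "default"
  sp <- xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns)
  sp_id <- xml2::xml_attr(sp, "id")
  comp <- xml2::xml_attr(sp, "compartment")
  if (!all(comp %in% .valid_compartments))
    stop("unknown compartment code in SBML: ",
         paste(setdiff(comp, .valid_compartments), collapse = ", "))
  base <- sub("^M_", "", sp_id)
  base <- vapply(seq_along(base), function(i)
    sub(paste0("_", comp[i], "$"), "", base[i]), character(1))
  compounds <- data.frame(base_id = base, compartment = comp,
                          stringsAsFactors = FALSE)
  pars <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pval <- setNames(as.numeric(xml2::xml_attr(pars, "value")),
                   xml2::xml_attr(pars, "id"))
  rx <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (!length(rx)) stop("SBML model without reactions")
  obj <- xml2::xml_find_all(
    doc, ".//fbc:listOfObjectives//fbc:fluxObjective", ns)
  bio_ids <- xml2::xml_attr(obj, "reaction")
  if (length(bio_ids) != 1)
    stop("SBML model must declare exactly one objective (biomass) reaction, ",
         "found ", length(bio_ids))
  tri <- list(); rid <- character(0); lb <- ub <- numeric(0)
  keys <- cpd_key(compounds$base_id, compounds$compartment)
  for (k in seq_along(rx)) {
    r <- rx[[k]]
    rid[k] <- xml2::xml_attr(r, "id")
    lbp <- xml2::xml_attr(r, "fbc:lowerFluxBound", ns)
    ubp <- xml2::xml_attr(r, "fbc:upperFluxBound", ns)
    lb[k] <- if (!is.na(lbp) && lbp %in% names(pval)) pval[[lbp]] else -1000
    ub[k] <- if (!is.na(ubp) && ubp %in% names(pval)) pval[[ubp]] else 1000
    # infinite/unparseable bounds are clamped to a finite magnitude
    if (!is.finite(lb[k])) lb[k] <- -1e6
    if (!is.finite(ub[k])) ub[k] <- 1e6
    for (side in c("listOfReactants", "listOfProducts")) {
      refs <- xml2::xml_find_all(r, paste0("./s:", side, "/s:speciesRef",
                                           "erence"), ns)
      if (!length(refs)) next
      sgn <- if (side == "listOfReactants") -1 else 1
      i <- match(xml2::xml_attr(refs, "species"), sp_id)
      st <- as.numeric(xml2::xml_attr(refs, "stoichiometry"))
      st[is.na(st)] <- 1
      tri[[length(tri) + 1L]] <- cbind(i, k, sgn * st)
    }
  }
  tri <- do.call(rbind, tri)
  S <- Matrix::sparseMatrix(i = tri[, 1], j = tri[, 2], x = tri[, 3],
                            dims = c(length(keys), length(rid)))
  reactions <- data.frame(
    id = sub("^R_", "", rid), lb = lb, ub = ub,
    is_biomass = rid %in% bio_ids,
    is_exchange = grepl("^R_EX_|^EX_", rid), stringsAsFactors = FALSE)
  metabolic_model(id, compounds, reactions, S, collection = collection)
}

.write_sbml <- function(model, path) {
  if (model$externalized)
    stop("SBML export stores raw models; write before externalizing")
  esc <- function(x) gsub("&", "&amp;", x, fixed = TRUE)
  sp_id <- paste0("M_", model$compounds$base_id, "_",
                  model$compounds$compartment)
  cmp <- unique(model$compounds$compartment)
  L <- c('<?xml version="1.0" encoding="UTF-8"?>',
         paste0('<sbml xmlns="', .sbml_ns[["s"]], '" xmlns:fbc="',
                .sbml_ns[["fbc"]],
                '" level="3" version="1" fbc:required="false">'),
         paste0('<model id="', esc(model$id), '" name="',
                esc(model$collection), '" fbc:strict="true">'),
         "<listOfCompartments>",
         paste0('<compartment id="', cmp, '" constant="true"/>'),
         "</listOfCompartments>", "<listOfSpecies>",
         paste0('<species id="', sp_id, '" compartment="',
                model$compounds$compartment,
                '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
                ' constant="false"/>'),
         "</listOfSpecies>", "<listOfParameters>")
  pl <- character(0)
  for (k in seq_len(nrow(model$reactions)))
    pl <- c(pl, paste0('<parameter id="bnd_lb_', k, '" value="',
                       format(model$reactions$lb[k], digits = 15),
                       '" constant="true"/>'),
            paste0('<parameter id="bnd_ub_', k, '" value="',
                   format(model$reactions$ub[k], digits = 15),
                   '" constant="true"/>'))
  L <- c(L, pl, "</listOfParameters>", "<listOfReactions>")
  for (k in seq_len(nrow(model$reactions))) {
    col <- model$S[, k]
    nzm <- which(col < 0); nzp <- which(col > 0)
    rid <- paste0(if (model$reactions$is_exchange[k] &&
                      !grepl("^EX_", model$reactions$id[k])) "R_EX_" else "R_",
                  model$reactions$id[k])
    L <- c(L, paste0('<reaction id="', esc(rid),
                     '" reversible="true" fast="false"',
                     ' fbc:lowerFluxBound="bnd_lb_', k,
                     '" fbc:upperFluxBound="bnd_ub_', k, '">'))
    if (length(nzm))
      L <- c(L, "<listOfReactants>",
             paste0('<speciesReference species="', sp_id[nzm],
                    '" stoichiometry="', format(-col[nzm], digits = 15),
                    '" constant="true"/>'),
             "</listOfReactants>")
    if (length(nzp))
      L <- c(L, "<listOfProducts>",
             paste0('<speciesReference species="', sp_id[nzp],
                    '" stoichiometry="', format(col[nzp], digits = 15),
                    '" constant="true"/>'),
             "</listOfProducts>")
    L <- c(L, "</reaction>")
  }
  bio_rid <- paste0("R_", model$reactions$id[model$biomass])
  L <- c(L, "</listOfReactions>",
         '<fbc:listOfObjectives fbc:activeObjective="obj">',
         '<fbc:objective fbc:id="obj" fbc:type="maximize">',
         "<fbc:listOfFluxObjectives>",
         paste0('<fbc:fluxObjective fbc:reaction="', bio_rid,
                '" fbc:coefficient="1"/>'),
         "</fbc:listOfFluxObjectives>", "</fbc:objective>",
         "</fbc:listOfObjectives>", "</model>", "</sbml>")
  writeLines(L, path)
}
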