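# Metabolic network container and gene-protein-reaction (GPR) rules.
#
# The network is the field's canonical stoichiometric-model shape: metabolites
# with compartments, reactions with bounds, a sparse stoichiometry, a boolean
# GPR over gene ids, and a single biomass objective. Both the pan-model and
# every derived strain model share this shape.

#' Construct a metabolic network
#'
#' @param metabolites tibble with columns `id`, `compartment` (one of
#'   `"c"`, `"p"`, `"e"`).
#' @param reactions tibble with columns `id`, `lower_bound`, `upper_bound`
#'   (mmol/h/gCDW), `subsystem`, `gpr` (boolean rule string over gene ids,
#'   `""` for non-genetic reactions) and `stoichiometry` (list column of
#'   named numeric vectors, metabolite id -> coefficient).
#' @param genes character vector of gene ids.
#' @param objective id of the biomass/objective reaction.
#' @return an object of class `metabolic_network`.
#' @export
metabolic_network <- function(metabolites, reactions, genes, objective) {
  metabolites <- as_tibble(metabolites)
  reactions <- as_tibble(reactions)
  stopifnot(all(c("id", "compartment") %in% names(metabolites)),
            all(c("id", "lower_bound", "upper_bound", "gpr",
                  "stoichiometry") %in% names(reactions)))
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  if (anyDuplicated(metabolites$id)) abort("duplicate metabolite ids")
  if (anyDuplicated(reactions$id)) abort("duplicate reaction ids")
  bad <- setdiff(unique(metabolites$compartment), c("c", "p", "e"))
  if (length(bad)) abort(paste0("unknown compartment(s): ", toString(bad)))
  if (any(reactions$lower_bound > reactions$upper_bound)) {
    abort("reaction bounds must satisfy lower <= upper")
  }
  used <- unique(unlist(lapply(reactions$stoichiometry, names)))
  missing_met <- setdiff(used, metabolites$id)
  if (length(missing_met)) {
    abort(paste0("stoichiometry references unknown metabolites: ",
                 toString(head(missing_met, 5))))
  }
  if (!objective %in% reactions$id) {
    abort(sprintf("objective reaction '%s' is not in the network", objective))
  }
  # GPRs are parsed at load time so malformed rules fail here, not mid-FBA
  ast <- lapply(reactions$gpr, parse_gpr)
  gpr_genes <- unique(unlist(lapply(ast, gpr_gene_ids)))
  missing_gene <- setdiff(gpr_genes, genes)
  if (length(missing_gene)) {
    abort(paste0("GPR references genes absent from the gene list: ",
                 toString(head(missing_gene, 5))))
  }
  # exchange reactions (EX_ prefix) must touch only extracellular metabolites
  comp_of <- setNames(metabolites$compartment, metabolites$id)
  is_ex <- startsWith(reactions$id, "EX_")
  for (i in which(is_ex)) {
    mets <- names(reactions$stoichiometry[[i]])
    if (any(comp_of[mets] != "e")) {
      abort(sprintf("exchange reaction '%s' touches non-extracellular metabolites",
                    reactions$id[i]))
    }
  }
  structure(
    list(metabolites = metabolites,
         reactions = mutate(reactions, gpr_ast = ast),
         genes = sort(unique(genes)),
         objective = objective),
    class = "metabolic_network"
  )
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %d metabolites, %d reactions, %d genes; objective: %s\n",
              nrow(x$metabolites), nrow(x$reactions), length(x$genes),
              x$objective))
  invisible(x)
}

#' Gene, reaction and metabolite counts of a network
#'
#' @param network a `metabolic_network`.
#' @return a tibble with columns `category` and `count`.
#' @export
model_counts <- function(network) {
  stopifnot(inherits(network, "metabolic_network"))
  tibble(category = c("genes", "reactions", "metabolites"),
         count = c(length(network$genes), nrow(network$reactions),
                   nrow(network$metabolites)))
}

#' Identify exchange reactions
#'
#' Exchange reactions follow the conventional `EX_` prefix and exchange a
#' single extracellular metabolite with the environment.
#'
#' @param network a `metabolic_network`.
#' @return character vector of reaction ids.
#' @export
exchange_reactions <- function(network) {
  network$reactions$id[startsWith(network$reactions$id, "EX_")]
}

# ---- GPR parsing and evaluation ---------------------------------------------

#' Parse a boolean gene-protein-reaction rule
#'
#' Grammar: `expr := term ("or" term)*`, `term := factor ("and" factor)*`,
#' `factor := gene | "(" expr ")"`. Operators are case-insensitive. The empty
#' rule parses to `NULL` (a non-genetic reaction, always catalyzable).
#'
#' @param rule GPR string, e.g. `"(g1 and g2) or g3"`.
#' @return a nested list AST, or `NULL` for the empty rule.
#' @export
parse_gpr <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  rule <- trimws(rule)
  if (!nzchar(rule)) return(NULL)
  tokens <- regmatches(rule, gregexpr("\\(|\\)|[^()[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  fail <- function(msg) abort(sprintf("malformed GPR '%s': %s", rule, msg))
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_term()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) fail("unexpected end of rule")
    if (t == "(") {
      e <- parse_expr()
      if (is.na(peek()) || take() != ")") fail("unbalanced parentheses")
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) {
      fail(sprintf("unexpected token '%s'", t))
    }
    t # gene literal
  }
  out <- parse_expr()
  if (pos <= length(tokens)) fail(sprintf("trailing token '%s'", tokens[pos]))
  out
}

gpr_gene_ids <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (is.character(ast)) return(ast)
  unique(unlist(lapply(ast$args, gpr_gene_ids)))
}

#' Evaluate a GPR rule over a gene set
#'
#' The empty rule evaluates to `TRUE` (non-genetic reactions are retained in
#' every strain model).
#'
#' @param expr a GPR string or a parsed AST from [parse_gpr()].
#' @param present character vector of genes present in the strain.
#' @return logical scalar.
#' @export
evaluate_gpr <- function(expr, present) {
  if (is.character(expr) && length(expr) == 1L) {
    # a raw rule string; parsing a bare gene literal is the literal itself
    expr <- parse_gpr(expr)
  }
  eval_ast <- function(ast) {
    if (is.null(ast)) return(TRUE)
    if (is.character(ast)) return(ast %in% present)
    vals <- vapply(ast$args, eval_ast, logical(1))
    if (ast$op == "and") all(vals) else any(vals)
  }
  eval_ast(expr)
}

#' Restrict a network to the reactions catalyzable by a gene set
#'
#' Reactions whose GPR evaluates to `FALSE` over `genes_present` are removed
#' (empty-GPR reactions are kept); metabolites no longer referenced by any
#' reaction are pruned.
#'
#' @param network a `metabolic_network`.
#' @param genes_present character vector of surviving gene ids.
#' @return a list with elements `network` (the restricted
#'   `metabolic_network`), `removed_genes`, `removed_reactions`.
#' @export
restrict_network <- function(network, genes_present) {
  stopifnot(inherits(network, "metabolic_network"))
  keep <- vapply(network$reactions$gpr_ast,
                 function(a) evaluate_gpr(a, genes_present), logical(1))
  reactions <- network$reactions[keep, , drop = FALSE]
  used <- unique(unlist(lapply(reactions$stoichiometry, names)))
  metabolites <- filter(network$metabolites, .data$id %in% used)
  surviving <- intersect(network$genes, genes_present)
  out <- structure(
    list(metabolites = metabolites,
         reactions = reactions,
         genes = surviving,
         objective = network$objective),
    class = "metabolic_network"
  )
  list(network = out,
       removed_genes = setdiff(network$genes, genes_present),
       removed_reactions = network$reactions$id[!keep])
}

# ---- COBRA-style JSON I/O ---------------------------------------------------

#' Write a network as COBRA-style JSON
#'
#' The layout mirrors the standard COBRA JSON schema (`metabolites`,
#' `reactions` with `metabolites` maps, `lower_bound`/`upper_bound`,
#' `gene_reaction_rule`, `subsystem`, `objective_coefficient`, `genes`), so
#' files round-trip through other constraint-based tooling.
#'
#' @param network a `metabolic_network`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cobra_json <- function(network, path) {
  stopifnot(inherits(network, "metabolic_network"))
  rxns <- purrr::pmap(
    list(network$reactions$id, network$reactions$stoichiometry,
         network$reactions$lower_bound, network$reactions$upper_bound,
         network$reactions$gpr, network$reactions$subsystem),
    function(id, st, lb, ub, gpr, subsystem) {
      list(id = id,
           metabolites = as.list(st),
           lower_bound = lb,
           upper_bound = ub,
           gene_reaction_rule = gpr,
           subsystem = subsystem,
           objective_coefficient = if (id == network$objective) 1 else 0)
    })
  obj <- list(
    id = "model",
    metabolites = purrr::map2(network$metabolites$id,
                              network$metabolites$compartment,
                              function(id, comp) list(id = id, compartment = comp)),
    reactions = rxns,
    genes = lapply(network$genes, function(g) list(id = g))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a COBRA-style JSON model
#'
#' @param path path to a JSON file written by [write_cobra_json()] or by
#'   other COBRA-compatible tools.
#' @return a `metabolic_network`.
#' @export
read_cobra_json <- function(path) {
  obj <- jsonlite::read_json(path)
  metabolites <- tibble(
    id = map_chr(obj$metabolites, "id"),
    compartment = map_chr(obj$metabolites, "compartment")
  )
  reactions <- tibble(
    id = map_chr(obj$reactions, "id"),
    lower_bound = map_dbl(obj$reactions, "lower_bound"),
    upper_bound = map_dbl(obj$reactions, "upper_bound"),
    subsystem = map_chr(obj$reactions, function(r) r$subsystem %||% ""),
    gpr = map_chr(obj$reactions, function(r) r$gene_reaction_rule %||% ""),
    stoichiometry = map(obj$reactions, function(r) {
      unlist(lapply(r$metabolites, as.numeric))
    })
  )
  obj_coef <- map_dbl(obj$reactions, function(r) r$objective_coefficient %||% 0)
  if (sum(obj_coef != 0) != 1L) {
    abort("model must declare exactly one objective reaction")
  }
  genes <- map_chr(obj$genes, "id")
  metabolic_network(metabolites, reactions, genes,
                    objective = reactions$id[which(obj_coef != 0)])
}
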