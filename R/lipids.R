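#' Parse a lipid shorthand name
#'
#' Understands the shorthand grammars produced by common identification and
#' targeted-panel software:
#' \itemize{
#'   \item `"PC 34:4"` — class, total carbons : total double bonds;
#'   \item `"Cer[NS] 34:1; Cer[NS](d18:1/16:0); [M+H]+"` — subclass bracket,
#'     per-chain composition (sphingoid `d` prefix), adduct suffix stripped;
#'   \item `"Plasmenyl-PC 30:0"` — vinyl-ether (plasmalogen) linkage, mapped
#'     to class `PC-P`; `"Plasmanyl-"` maps to `-O`;
#'   \item `"PC-O 34:1"` / `"PC(O-38:6)"` — ether classes;
#'   \item `"PC(O-38:6) / PC(P-38:5)"` — unresolved O-/P- alternatives: the
#'     O- form is kept as the primary identity, the P- form recorded under
#'     `ambiguous_alternatives`.
#' }
#' Unparseable input raises an error naming the offending token; there is no
#' silent guessing.
#'
#' @param name a single lipid name.
#' @return list with `raw_name`, `lipid_class`, `total_carbons`,
#'   `total_double_bonds`, `chains` (possibly NULL; each chain has
#'   `carbons`, `double_bonds`, `sphingoid`), `ambiguous_alternatives`
#'   (possibly NULL).
#' @examples
#' parseLipidName("PC 34:4")
#' parseLipidName("Cer[NS] 34:1; Cer[NS](d18:1/16:0); [M+H]+")
#' @export
parseLipidName <- function(name) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  segs <- trimws(strsplit(name, ";", fixed = TRUE)[[1]])
  segs <- segs[nzchar(segs)]
  # drop adduct segments such as "[M+H]+" / "[M-H]-"
  segs <- segs[!grepl("^\\[M[+-][^]]*\\][+-]?$", segs)]
  if (!length(segs))
    stop("no lipid token in name: '", name, "'")

  primary <- NULL
  alternatives <- NULL
  chains <- NULL

  parseSimple <- function(tok) {
    # PC 34:4 | Cer[NS] 34:1 | PC-O 34:1 | SPB 18:1
    m <- regmatches(tok, regexec(
      "^([A-Za-z0-9]+(?:-[OP])?)(\\[[A-Za-z0-9]+\\])?[ ]+(\\d+):(\\d+)$", tok))[[1]]
    if (length(m))
      return(list(lipid_class = m[2], total_carbons = as.integer(m[4]),
                  total_double_bonds = as.integer(m[5])))
    # Plasmenyl-PC 30:0 / Plasmanyl-PC 30:0
    m <- regmatches(tok, regexec(
      "^(Plasmenyl|Plasmanyl)-([A-Za-z0-9]+)[ ]+(\\d+):(\\d+)$", tok))[[1]]
    if (length(m)) {
      link <- if (m[2] == "Plasmenyl") "P" else "O"
      return(list(lipid_class = paste0(m[3], "-", link),
                  total_carbons = as.integer(m[4]),
                  total_double_bonds = as.integer(m[5])))
    }
    # PC(O-38:6) ether form
    m <- regmatches(tok, regexec(
      "^([A-Za-z0-9]+)\\(([OP])-(\\d+):(\\d+)\\)$", tok))[[1]]
    if (length(m))
      return(list(lipid_class = paste0(m[2], "-", m[3]),
                  total_carbons = as.integer(m[4]),
                  total_double_bonds = as.integer(m[5])))
    NULL
  }

  parseChains <- function(tok) {
    # Cer[NS](d18:1/16:0)
    m <- regmatches(tok, regexec(
      "^([A-Za-z0-9]+(?:-[OP])?)(\\[[A-Za-z0-9]+\\])?\\(([^)]+)\\)$", tok))[[1]]
    if (!length(m)) return(NULL)
    parts <- strsplit(m[4], "/", fixed = TRUE)[[1]]
    ch <- lapply(parts, function(p) {
      cm <- regmatches(p, regexec("^(d?)(\\d+):(\\d+)$", trimws(p)))[[1]]
      if (!length(cm)) return(NULL)
      list(carbons = as.integer(cm[3]), double_bonds = as.integer(cm[4]),
           sphingoid = cm[2] == "d")
    })
    if (any(vapply(ch, is.null, logical(1)))) return(NULL)
    list(lipid_class = m[2], chains = ch)
  }

  for (seg in segs) {
    if (grepl(" / ", seg, fixed = TRUE)) {
      sides <- trimws(strsplit(seg, " / ", fixed = TRUE)[[1]])
      parsed <- lapply(sides, parseSimple)
      if (any(vapply(parsed, is.null, logical(1))))
        stop("unparseable lipid token: '", seg, "'")
      if (is.null(primary)) primary <- parsed[[1]]
      alternatives <- c(alternatives, parsed[-1])
      next
    }
    s <- parseSimple(seg)
    if (!is.null(s)) {
      if (is.null(primary)) primary <- s
      next
    }
    chTok <- parseChains(seg)
    if (!is.null(chTok)) {
      chains <- chTok$chains
      if (is.null(primary)) {
        primary <- list(
          lipid_class = chTok$lipid_class,
          total_carbons = sum(vapply(chains, `[[`, integer(1), "carbons")),
          total_double_bonds = sum(vapply(chains, `[[`, integer(1),
                                          "double_bonds")))
      }
      next
    }
    stop("unparseable lipid token: '", seg, "'")
  }
  if (is.null(primary))
    stop("unparseable lipid name: '", name, "'")
  if (primary$total_carbons <= 0)
    stop("total carbons must be positive in '", name, "'")
  if (!is.null(chains)) {
    if (sum(vapply(chains, `[[`, integer(1), "carbons")) !=
        primary$total_carbons ||
        sum(vapply(chains, `[[`, integer(1), "double_bonds")) !=
        primary$total_double_bonds)
      stop("chain composition does not sum to totals in '", name, "'")
  }
  list(raw_name = name,
       lipid_class = primary$lipid_class,
       total_carbons = primary$total_carbons,
       total_double_bonds = primary$total_double_bonds,
       chains = chains,
       ambiguous_alternatives = alternatives)
}

#' Parse a vector of lipid names into a catalog table
#'
#' @param names character vector of lipid shorthand names.
#' @return data.frame with `raw_name, lipid_class, total_carbons,
#'   total_double_bonds`.
#' @export
parseLipidCatalog <- function(names) {
  parsed <- lapply(names, parseLipidName)
  data.frame(
    raw_name = names,
    lipid_class = vapply(parsed, `[[`, character(1), "lipid_class"),
    total_carbons = vapply(parsed, `[[`, integer(1), "total_carbons"),
    total_double_bonds = vapply(parsed, `[[`, integer(1),
                                "total_double_bonds"),
    stringsAsFactors = FALSE)
}

#' Build lipid sets by class, total chain length and total unsaturation
#'
#' One feature set per observed lipid class, per distinct total carbon
#' number, and per distinct total double-bond count, so every species lands
#' in exactly three sets. Ambiguous O-/P- species contribute through their
#' primary identity only.
#'
#' @param species a catalog from [parseLipidCatalog()] (or a character
#'   vector of names, parsed on the fly).
#' @return named list of feature sets; each has `set_id`, `kind`
#'   (`class`/`chain_length`/`unsaturation`) and `members` (raw names).
#' @export
buildLipidSets <- function(species) {
  if (is.character(species)) species <- parseLipidCatalog(species)
  if (!nrow(species)) return(list())
  sets <- list()
  addSets <- function(keys, kind, prefix) {
    for (k in sort(unique(keys))) {
      id <- paste0(prefix, k)
      sets[[id]] <<- list(set_id = id, kind = kind,
                          members = species$raw_name[keys == k])
    }
  }
  addSets(species$lipid_class, "class", "class:")
  addSets(species$total_carbons, "chain_length", "chain_length:")
  addSets(species$total_double_bonds, "unsaturation", "unsaturation:")
  sets
}
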