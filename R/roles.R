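#' Locational roles and phenotype vocabularies
#'
#' Each neuronal segment role maps to exactly one OWL-dialect property and
#' one simple-dialect (shortcut) predicate. The OWL properties follow the
#' readable `ilxtr` namespace; the axon-to-sensory course property is a
#' documented placeholder (only its shortcut form is fixed by the query
#' conventions).
#'
#' @name roles
NULL

# role -> property tables. Order here is the canonical serialization order
# for locational restrictions (soma, dendrite, axon, axon-to-sensory,
# axon terminal, sensory terminal).
ROLE_TABLE <- data.frame(
  role = c("soma", "dendrite", "axon", "axon_to_sensory_terminal",
           "axon_terminal", "sensory_terminal"),
  owl_property = c(
    "ilxtr:hasSomaLocatedIn",
    "ilxtr:hasDendriteLocatedIn",
    "ilxtr:hasAxonLocatedIn",
    "ilxtr:hasAxonToSensoryTerminalIn",
    "ilxtr:hasAxonPresynapticElementIn",
    "ilxtr:hasAxonSensorySubcellularElementIn"
  ),
  simple_predicate = c(
    "ilxtr:hasSomaLocation",
    "ilxtr:hasDendriteLocation",
    "ilxtr:hasAxonLocation",
    "ilxtr:hasAxonToSensoryTerminal",
    "ilxtr:hasAxonTerminalLocation",
    "ilxtr:hasAxonSensoryLocation"
  ),
  stringsAsFactors = FALSE
)

#' Location roles
#'
#' @return character vector of the six neuronal segment roles, in canonical
#'   order.
#' @export
location_roles <- function() ROLE_TABLE$role

#' Role/property mapping table
#'
#' @return data.frame with columns `role`, `owl_property`,
#'   `simple_predicate`; the mapping is total over roles and bijective on
#'   predicates.
#' @export
role_properties <- function() ROLE_TABLE

role_to_owl <- function(role) {
  ROLE_TABLE$owl_property[match(role, ROLE_TABLE$role)]
}
role_to_simple <- function(role) {
  ROLE_TABLE$simple_predicate[match(role, ROLE_TABLE$role)]
}
owl_to_role <- function(prop) {
  ROLE_TABLE$role[match(prop, ROLE_TABLE$owl_property)]
}
simple_to_role <- function(pred) {
  ROLE_TABLE$role[match(pred, ROLE_TABLE$simple_predicate)]
}

# Roles that count as the axonal course ("via") in queries: the
# axon-to-sensory course is treated as an axon-course location.
AXON_COURSE_ROLES <- c("axon", "axon_to_sensory_terminal")
# Roles that count as destinations.
DESTINATION_ROLES <- c("axon_terminal", "sensory_terminal")

# ANS subdivision phenotype vocabulary: division x ganglionic stage.
ANS_TABLE <- local({
  div <- c("sympathetic", "parasympathetic", "enteric")
  stage <- c("pre_ganglionic", "post_ganglionic", "unspecified")
  g <- expand.grid(stage = stage, division = div, stringsAsFactors = FALSE)
  cap <- function(s) paste0(toupper(substring(s, 1, 1)), substring(s, 2))
  stage_lab <- c(pre_ganglionic = "Pre-Ganglionic",
                 post_ganglionic = "Post-Ganglionic",
                 unspecified = "")
  lab <- ifelse(g$stage == "unspecified",
                paste(cap(g$division), "phenotype"),
                paste(cap(g$division), stage_lab[g$stage], "phenotype"))
  camel <- ifelse(g$stage == "unspecified",
                  paste0(cap(g$division), "Phenotype"),
                  paste0(cap(g$division),
                         gsub("-", "", stage_lab[g$stage]), "Phenotype"))
  data.frame(token = paste(g$division, g$stage, sep = ":"),
             division = g$division, stage = g$stage,
             label = lab, curie = paste0("ilxtr:", camel),
             stringsAsFactors = FALSE)
})

#' ANS subdivision phenotype vocabulary
#'
#' The autonomic subdivision of a population is one of sympathetic,
#' parasympathetic, or enteric, optionally qualified as pre- or
#' post-ganglionic. Each combination has a phenotype class CURIE and a
#' display label (e.g. `"Sympathetic Pre-Ganglionic phenotype"`).
#'
#' @return data.frame with columns `token` (`division:stage`), `division`,
#'   `stage`, `label`, `curie`.
#' @export
ans_phenotypes <- function() ANS_TABLE

#' Build an ANS phenotype token
#'
#' @param division one of `"sympathetic"`, `"parasympathetic"`, `"enteric"`.
#' @param stage one of `"pre_ganglionic"`, `"post_ganglionic"`,
#'   `"unspecified"`.
#' @return token string usable in [neuron_population()] phenotypes.
#' @export
ans_phenotype <- function(division, stage = "unspecified") {
  token <- paste(division, stage, sep = ":")
  if (!token %in% ANS_TABLE$token) {
    stop("unknown ANS phenotype: ", token)
  }
  token
}

ans_label <- function(token) ANS_TABLE$label[match(token, ANS_TABLE$token)]
ans_curie <- function(token) ANS_TABLE$curie[match(token, ANS_TABLE$token)]
ans_from_curie <- function(curie) ANS_TABLE$token[match(curie, ANS_TABLE$curie)]

CIRCUIT_ROLES <- c(intrinsic = "ilxtr:IntrinsicPhenotype",
                   motor = "ilxtr:MotorPhenotype",
                   sensory = "ilxtr:SensoryPhenotype",
                   projection = "ilxtr:ProjectionPhenotype")
FUNCTIONAL_ROLES <- c(excitatory = "ilxtr:ExcitatoryPhenotype",
                      inhibitory = "ilxtr:InhibitoryPhenotype")

SEX_CURIES <- c(male = "PATO:0000384", female = "PATO:0000383")
SEX_FROM_CURIE <- stats::setNames(names(SEX_CURIES), SEX_CURIES)
opposite_sex <- function(sex) c(male = "female", female = "male")[[sex]]

# Base class markers distinguishing the two provenance kinds.
BASE_MARKERS <- c(literature = "ilxtr:NeuronSparcNlp",
                  expert_model = "ilxtr:NeuronApinatSimple")
MARKER_TO_KIND <- stats::setNames(names(BASE_MARKERS), BASE_MARKERS)

# Entity classes whose subclass closure defines "nerve-like" structures.
NERVE_LIKE_LABELS <- c("nerve", "nerve plexus", "nerve fiber")
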