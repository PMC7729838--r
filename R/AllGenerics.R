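#' Number of patients (transactions) behind an object
#'
#' @param x a [TransactionDB-class] or [ComorbidityNetwork-class].
#' @return integer count, including zero-comorbidity transactions.
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' Item (morbidity category) labels
#'
#' @param x a [TransactionDB-class] or [AssociationRuleSet-class].
#' @return character vector of category labels.
#' @export
setGeneric("itemLabels", function(x) standardGeneric("itemLabels"))

#' Per-item patient counts
#'
#' @param x a [TransactionDB-class].
#' @return named integer vector: number of transactions containing each item.
#' @export
setGeneric("itemCounts", function(x) standardGeneric("itemCounts"))

#' Transactions as a list of label sets
#'
#' @param x a [TransactionDB-class].
#' @return named list of character vectors (sorted labels), one per patient.
#' @export
setGeneric("transactionList", function(x) standardGeneric("transactionList"))

#' Rule quality metrics
#'
#' @param x an [AssociationRuleSet-class].
#' @return data.frame of support, confidence, lift (plus counts when mined
#'   from data), one row per rule.
#' @export
setGeneric("ruleQuality", function(x) standardGeneric("ruleQuality"))

#' Community assignment of a partition
#'
#' @param x a [CommunityPartition-class].
#' @return named integer vector mapping node labels to community ids.
#' @export
setGeneric("communityAssignment",
           function(x) standardGeneric("communityAssignment"))
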