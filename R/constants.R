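## Canonical orders shared across the package.  These orders are
## load-bearing: parameter records, the state roster, the output map and
## the compiled core all index by them.

.TISSUES <- c("fat", "liver", "kidney", "richly", "slowly",
              "skin", "stomach", "intestine", "lung")
.VOLUME_COMPARTMENTS <- c("arterial", "venous", "lung", "fat", "liver",
                          "kidney", "richly", "slowly", "skin",
                          "stomach", "intestine")
.PERFUSED <- .TISSUES                       # 9 perfused compartments
.SAT_PATHWAYS <- c("liver1", "liver2", "lung", "kidney")
.FO_PATHWAYS  <- c("liver", "lung", "kidney", "stomach", "intestine")
.PATHWAYS <- c(paste0("sat_", .SAT_PATHWAYS), paste0("fo_", .FO_PATHWAYS))

.PARTITION_TISSUES <- c("fat", "liver", "kidney", "richly", "slowly",
                        "skin", "lung", "stomach", "intestine")
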