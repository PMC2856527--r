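"panelist_id","component_id","considered","impact","comment"
"p01","utility","yes","negative",""
"p01","efficiency","yes","mixed",""
"p01","fairness","yes","mixed",""
"p01","system_capacity","yes","mixed",""
"p01","stakeholder_pressures","no","not_applicable",""
"p01","political_context","yes","none",""
"p02","utility","yes","negative",""
"p02","efficiency","yes","mixed",""
"p02","fairness","yes","negative",""
"p02","system_capacity","yes","negative",""
"p02","stakeholder_pressures","no","not_applicable",""
"p02","political_context","yes","none",""
"p03","utility","yes","mixed",""
"p03","efficiency","yes","negative",""
"p03","fairness","yes","mixed",""
"p03","system_capacity","yes","mixed",""
"p03","stakeholder_pressures","no","not_applicable",""
"p03","political_context","yes","none",""
"p04","utility","yes","negative",""
"p04","efficiency","yes","mixed",""
"p04","fairness","yes","negative",""
"p04","system_capacity","yes","mixed",""
"p04","stakeholder_pressures","yes","mixed",""
"p04","political_context","yes","none",""
"p05","utility","yes","negative",""
"p05","efficiency","yes","negative",""
"p05","fairness","yes","mixed",""
"p05","system_capacity","yes","positive",""
"p05","stakeholder_pressures","yes","mixed",""
"p05","political_context","yes","none",""
"p06","utility","yes","negative",""
"p06","efficiency","yes","negative",""
"p06","fairness","yes","mixed",""
"p06","system_capacity","yes","negative",""
"p06","stakeholder_pressures","yes","negative",""
"p06","political_context","yes","none",""
"p07","utility","yes","mixed",""
"p07","efficiency","yes","positive",""
"p07","fairness","yes","mixed",""
"p07","system_capacity","yes","negative",""
"p07","stakeholder_pressures","yes","positive",""
"p07","political_context","yes","none",""
"p08","utility","yes","mixed",""
"p08","efficiency","yes","positive",""
"p08","fairness","yes","positive",""
"p08","system_capacity","yes","positive",""
"p08","stakeholder_pressures","yes","positive",""
"p08","political_context","yes","none",""
"p09","utility","yes","negative",""
"p09","efficiency","yes","positive",""
"p09","fairness","yes","mixed",""
"p09","system_capacity","yes","positive",""
"p09","stakeholder_pressures","yes","mixed",""
"p09","political_context","yes","none",""
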