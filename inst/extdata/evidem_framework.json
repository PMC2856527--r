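{
  "clusters": [
    {
      "id": "Q",
      "label": "Quality of evidence"
    },
    {
      "id": "D",
      "label": "Disease impact"
    },
    {
      "id": "I",
      "label": "Intervention"
    },
    {
      "id": "E",
      "label": "Economics"
    }
  ],
  "components": [
    {
      "id": "Q1",
      "cluster_id": "Q",
      "label": "Adherence to requirements of decisionmaking body",
      "low_anchor": "Low adherence",
      "high_anchor": "High adherence",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "Q2",
      "cluster_id": "Q",
      "label": "Completeness and consistency of reporting evidence",
      "low_anchor": "Many gaps/inconsistent",
      "high_anchor": "Complete and consistent",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "Q3",
      "cluster_id": "Q",
      "label": "Relevance and validity of evidence",
      "low_anchor": "Low relevance/validity",
      "high_anchor": "High relevance/validity",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "D1",
      "cluster_id": "D",
      "label": "Disease severity",
      "low_anchor": "Not severe",
      "high_anchor": "Very severe",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "D2",
      "cluster_id": "D",
      "label": "Size of population",
      "low_anchor": "Very rare disease",
      "high_anchor": "Common disease",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "I1",
      "cluster_id": "I",
      "label": "Clinical guidelines",
      "low_anchor": "No recommendation",
      "high_anchor": "Strong recommendation",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "I2",
      "cluster_id": "I",
      "label": "Comparative interventions limitations",
      "low_anchor": "No or very minor limitations",
      "high_anchor": "Major limitations",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "I3",
      "cluster_id": "I",
      "label": "Improvement of efficacy/effectiveness",
      "low_anchor": "Lower than comparators",
      "high_anchor": "Major improvement",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "I4",
      "cluster_id": "I",
      "label": "Improvement of safety & tolerability",
      "low_anchor": "Lower than comparators",
      "high_anchor": "Major improvement",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "I5",
      "cluster_id": "I",
      "label": "Improvement of patient reported outcomes",
      "low_anchor": "Worse patient reported outcomes than comparators",
      "high_anchor": "Major improvement",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "I6",
      "cluster_id": "I",
      "label": "Public health interest",
      "low_anchor": "No risk reduction",
      "high_anchor": "Major risk reduction",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "I7",
      "cluster_id": "I",
      "label": "Type of medical service",
      "low_anchor": "Minor service",
      "high_anchor": "Major service (e.g. cure)",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "E1",
      "cluster_id": "E",
      "label": "Budget impact on health plan",
      "low_anchor": "Substantial additional expenditures",
      "high_anchor": "Substantial savings",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "E2",
      "cluster_id": "E",
      "label": "Cost-effectiveness of intervention",
      "low_anchor": "Not cost-effective",
      "high_anchor": "Highly cost-effective",
      "weightable": true,
      "scoreable": true
    },
    {
      "id": "E3",
      "cluster_id": "E",
      "label": "Impact on other spending",
      "low_anchor": "Substantial additional spending",
      "high_anchor": "Substantial savings",
      "weightable": true,
      "scoreable": true
    }
  ],
  "extrinsic": [
    {
      "id": "utility",
      "label": "Goals of healthcare - utility",
      "definition": "Alignment with the goal of healthcare to maintain normal functioning; the principle of producing the greatest benefit for the greatest number.",
      "group": "ethical_framework"
    },
    {
      "id": "efficiency",
      "label": "Opportunity costs - efficiency",
      "definition": "Opportunity costs: resources or interventions forgone if this intervention is used; maximizing health impact for a given level of resources, at patient and society level.",
      "group": "ethical_framework"
    },
    {
      "id": "fairness",
      "label": "Population priority & access - fairness",
      "definition": "Population priorities and access: treating like cases alike, different cases differently, and priority to the worst-off.",
      "group": "ethical_framework"
    },
    {
      "id": "system_capacity",
      "label": "System capacity and appropriate use of intervention",
      "definition": "Capacity of the healthcare system to implement the intervention and ensure appropriate use: infrastructure, skills, legislation, risks of inappropriate use.",
      "group": "other_components"
    },
    {
      "id": "stakeholder_pressures",
      "label": "Stakeholder pressures",
      "definition": "Pressures and interests of stakeholder groups surrounding the intervention and how they may affect decisionmakers' values.",
      "group": "other_components"
    },
    {
      "id": "political_context",
      "label": "Political/historical context",
      "definition": "Political priorities and historical context, including habits, traditions and precedence.",
      "group": "other_components"
    }
  ],
  "weight_scale": [1, 5],
  "score_scale": [0, 3]
}
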