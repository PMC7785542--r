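{
  "schema_version": "1.0",
  "profiles": [
    {
      "product_id": "FIX-DAAAP-1",
      "name": "synthetic-daaap-like",
      "approval_year": 2017,
      "review_division": "DAAAP",
      "designations": [
        "orphan"
      ],
      "indication": "chronic_pain",
      "benefit": {
        "condition_severity": "severe",
        "condition_prevalence": "rare_orphan",
        "treatment_availability": "none_exist",
        "durability": "consistent_substantial",
        "orphan_designation": true,
        "verbatim": null
      },
      "risks": [
        {
          "risk": {
            "term": "hepatotoxicity",
            "severity": "severe",
            "ctcae_grade": null,
            "frequency_band": "high",
            "frequency_percent": null,
            "nonclinical_only": false,
            "resolved_no_risk": false,
            "severity_override": false,
            "verbatim": "hepatotoxicity"
          },
          "mitigations": [
            {
              "kind": "rems",
              "burden_value": null,
              "verbatim": null
            },
            {
              "kind": "postmarketing_study_registry",
              "burden_value": null,
              "verbatim": null
            }
          ]
        }
      ]
    }
  ]
}
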