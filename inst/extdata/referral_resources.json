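{
  "comment": "Synthetic local referral resource list for the printable dashboard summary. Replace with site-specific agencies at deployment.",
  "resources": [
    {"name": "Community Recovery Center (synthetic)", "phone": "555-0101", "services": "Outpatient counseling, groups"},
    {"name": "Harbor Health Treatment Clinic (synthetic)", "phone": "555-0102", "services": "Medication-assisted treatment"},
    {"name": "24/7 Substance Use Helpline (synthetic)", "phone": "555-0199", "services": "Phone support and referrals"}
  ]
}
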