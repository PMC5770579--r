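{
  "version": "tailoring-default-1",
  "comment": "Decision rules for the computer-tailored intervention session. The drug ranking is the expert harm ordering used to break ties (opioids highest, cannabis lowest); the eligible set excludes tobacco and alcohol because the intervention targets risky drug use. The stage->process mapping follows canonical transtheoretical-model assignments; each (stage, purpose) cell names exactly 3 change-process modules.",
  "drug_ranking": [
    "opioids",
    "amphetamine_type_stimulants",
    "cocaine",
    "sedatives",
    "inhalants",
    "hallucinogens",
    "other",
    "tobacco",
    "alcohol",
    "cannabis"
  ],
  "eligible_substances": [
    "cannabis",
    "cocaine",
    "amphetamine_type_stimulants",
    "inhalants",
    "sedatives",
    "hallucinogens",
    "opioids",
    "other"
  ],
  "treatment_cutpoint": 27,
  "six_month_days": 183,
  "schedule_days": 30,
  "stage_gap_days": {
    "precontemplation": 3,
    "contemplation": 2,
    "preparation": 1,
    "action": 1,
    "maintenance": 2
  },
  "pac_window_days": 7,
  "pac_windows": 4,
  "reminder_lead_days": [3, 1],
  "send_time": "10:00",
  "stage_modules": {
    "quit": {
      "precontemplation": ["pros_of_change", "consciousness_raising", "dramatic_relief"],
      "contemplation": ["pros_of_change", "self_reevaluation", "environmental_reevaluation"],
      "preparation": ["self_liberation", "small_steps", "helping_relationships"],
      "action": ["counter_conditioning", "stimulus_control", "reinforcement_management"],
      "maintenance": ["relapse_prevention", "helping_relationships", "reinforcement_management"]
    },
    "seek_treatment": {
      "precontemplation": ["pros_of_treatment", "consciousness_raising", "treatment_options_education"],
      "contemplation": ["pros_of_treatment", "treatment_options_education", "self_reevaluation"],
      "preparation": ["warm_handoff", "appointment_planning", "helping_relationships"],
      "action": ["treatment_adherence", "helping_relationships", "reinforcement_management"],
      "maintenance": ["relapse_prevention", "treatment_adherence", "helping_relationships"]
    }
  },
  "goal_menus": {
    "quit": {
      "precontemplation": ["read_about_risks", "list_three_pros", "track_my_use"],
      "contemplation": ["list_three_pros", "tell_someone_i_trust", "pick_a_change_date"],
      "preparation": ["set_quit_date", "remove_supplies", "tell_someone_i_trust"],
      "action": ["avoid_one_trigger", "plan_substitute_activity", "ask_for_support"],
      "maintenance": ["review_my_plan", "plan_for_high_risk_day", "help_someone_else"]
    },
    "seek_treatment": {
      "precontemplation": ["read_treatment_options", "list_three_pros_of_treatment", "ask_provider_one_question"],
      "contemplation": ["read_treatment_options", "discuss_options_with_provider", "list_three_pros_of_treatment"],
      "preparation": ["call_agency_with_provider", "set_first_appointment", "arrange_transport"],
      "action": ["keep_next_appointment", "ask_for_support", "track_my_progress"],
      "maintenance": ["keep_next_appointment", "review_my_plan", "plan_for_high_risk_day"]
    }
  }
}
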