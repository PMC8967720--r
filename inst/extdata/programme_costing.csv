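label,basis,quantity,unit,unit_cost,share_divisor,capital,lifetime_years,annuity_rate,annuity_timing
link_worker,per_participant,0.5,hour,33.83,1,,,,
coordinator,per_group,36,hour,33.83,1,,,,
introductory_sessions,per_participant,0.75,hour,29.43,1,,,,
pedometers,per_participant,1,item,9.95,1,,,,
equipment_other,per_group,1,item,,1,136.27,5,0.035,in_advance
leader_preparation,per_session,0.5,hour,29.43,1,,,,
leader_travel,per_session,0.5,hour,29.43,1,,,,
leader_delivery,per_session,1.5,hour,29.43,1,,,,
refreshments,per_session,9.708125,item,1.00,1,,,,
printed_materials,per_participant,1,set,2.00,1,,,,
venue_hire,per_session,1.5,hour,17.32,1,,,,
trainer_time,per_programme_share,10.5,hour,33.83,16,,,,
trainee_leader_time,per_programme_share,10.5,hour,29.43,4,,,,
training_venue,per_programme_share,10.5,hour,29.43,4,,,,
training_manual,per_programme_share,1,item,12.00,4,,,,
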