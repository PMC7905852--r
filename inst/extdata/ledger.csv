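name,kind,quantity,unit_cost,useful_life_years
program_director,personnel,1,18333.78,
program_coordinator,personnel,1,12213.4,
administration_officer,personnel,1,7543.48,
office_space,capital,1,9422.51,
data_entry_clerk,personnel,1,5713.69,
finance_officer,personnel,1,5713.69,
health_educators,personnel,58,7543.481034,
external_consultant,personnel,1,555.69,
logistics_social_worker,personnel,1,7543.48,
transportation_drivers,personnel,20,4381.772,
vehicles_and_maintenance,capital,20,56820,8
electronic_projectors,equipment,19,325.7331579,1
computers_laptops,equipment,61,390.8795082,1
transport_allowance,welfare,602,60.93011628,
electricity_utility,consumable,12000,0.066,
telephone_utility,consumable,70,39.088,
hotel_accommodation,welfare,50104,4.034268721,
respiratory_rate_timers,equipment,49397,44,
miscellaneous,miscellaneous,1,12000,
training_refreshments,welfare,53162,5.023612167,
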