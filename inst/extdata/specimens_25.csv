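individual_id,total_length_cm,age,sex,maturity
OCS-1-1,191.8,5,male,mature
OCS-1-9,190.0,5,female,immature
OCS-4-2,158.9,5,male,immature
OCS-4-4,179.5,7,male,mature
OCS-4-7,185.0,9,female,mature
OCS-4-9,176.7,7,male,immature
OCS-5-1,175.4,6,female,immature
OCS-5-4,189.1,7,male,mature
OCS-6-1,168.0,6,male,immature
OCS-6-4,172.6,11,female,immature
OCS-6-5,230.2,14,male,immature
OCS-6-8,164.4,7,male,immature
OCS-6-10,235.0,16,female,mature
OCS-6-11,227.4,14,male,mature
OCS-9-1,205.5,12,male,mature
OCS-9-3,167.1,8,male,immature
OCS-9-4,170.0,7,male,immature
OCS-10-1,242.0,13,female,mature
OCS-2-10,171.3,9,female,immature
OCS-8-1,165.6,10,female,mature
OCS-8-2,150.0,9,female,immature
OCS-8-3,142.8,6,female,immature
OCS-8-10,153.6,9,male,immature
OCS-9-10,165.0,8,male,immature
OCS-34-8,160.3,4,female,immature
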