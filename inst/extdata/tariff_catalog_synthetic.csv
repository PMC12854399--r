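source,code,description,tariff_eur,year
GHS,1794,"Day hospitalization for pump adjustment (principal diagnosis Z451) - synthetic placeholder tariff",702.00,2024
NGAP,INIT-CL,"Closed-loop initiation, long office visit - synthetic placeholder tariff",120.00,2024
NGAP,TCG,"Teleconsultation - synthetic placeholder tariff",30.00,2024
NGAP,CSD,"Specialist diabetology consultation - synthetic placeholder tariff",57.00,2024
NABM,HGLY,"Laboratory glucose panel - synthetic placeholder tariff",12.15,2024
LPP,TLS-3M,"Telemonitoring package, 3 months - synthetic placeholder tariff",330.00,2024
LPP,CL-RENT,"Closed-loop device and consumable rental, per month - synthetic placeholder tariff",600.00,2024
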