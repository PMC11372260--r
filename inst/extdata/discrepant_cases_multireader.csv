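case_id,subtype,stage,reader_id,tmtv_cm3,adjudicator_note
H15,HL,4,reader1,275,Spleen
H15,HL,4,reader2,129,Spleen
H15,HL,4,reader3,282,Spleen
F02,FL,4,reader1,426,Spleen
F02,FL,4,reader2,399,Spleen
F02,FL,4,reader3,456,Spleen
F02,FL,4,reader4,252,Spleen
F05,FL,4,reader1,1680,Spleen
F05,FL,4,reader2,1706,Spleen
F05,FL,4,reader3,1650,Spleen
F05,FL,4,reader4,567,Spleen
B10,DLBCL,4,reader1,786,Spleen
B10,DLBCL,4,reader2,788,Spleen
B10,DLBCL,4,reader3,49,Spleen
B16,DLBCL,4,reader1,1223,Spleen
B16,DLBCL,4,reader2,546,Spleen
B16,DLBCL,4,reader3,509,Spleen
H11,HL,4,reader1,178,Physiologic uptake removed = 139 cm3; manual addition of small multifocal uptake in BM; neck and retroperitoneal increased to 231 cm3
H11,HL,4,reader2,229,Physiologic uptake removed = 139 cm3; manual addition of small multifocal uptake in BM; neck and retroperitoneal increased to 231 cm3
H11,HL,4,reader3,137,Physiologic uptake removed = 139 cm3; manual addition of small multifocal uptake in BM; neck and retroperitoneal increased to 231 cm3
H11,HL,4,reader4,159,Physiologic uptake removed = 139 cm3; manual addition of small multifocal uptake in BM; neck and retroperitoneal increased to 231 cm3
B05,DLBCL,4,reader1,272,Manual editing of myocardial uptake
B05,DLBCL,4,reader2,321,Manual editing of myocardial uptake
B05,DLBCL,4,reader3,318,Manual editing of myocardial uptake
F09,FL,4,reader1,246,Manual editing of kidneys and ureter
F09,FL,4,reader2,194,Manual editing of kidneys and ureter
F09,FL,4,reader3,196,Manual editing of kidneys and ureter
F09,FL,4,reader4,199,Manual editing of kidneys and ureter
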