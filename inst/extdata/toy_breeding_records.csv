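mating_id,dam_id,sire_id,mating_date,birth_date,born,weaned,males_weaned,females_weaned,stock
M1,D1,S1,2014-01-05,2014-03-01,6,5,3,2,BW
M1,D1,S1,2014-01-05,2014-03-01,6,5,3,2,BW
M1,D1,S1,2014-01-05,2014-04-15,5,6,3,3,BW
M2,D2,S2,2015-02-01,2015-13-40,4,4,2,2,BW
M2,D2,S2,2015-02-01,2015-05-01,4,,2,2,BW
M3,D3,S3,2016-01-01,2016-03-01,5,5,2,3,
M4,,S4,2016-02-01,2016-04-01,6,6,3,3,BW
M2,D2,S2,2015-02-01,2015-06-20,5,4,1,2,BW
M1,D1,S1,2014-01-05,2014-06-01,7,6,3,3,BW
M2,D2,S2,2015-02-01,2015-08-01,6,5,2,3,BW
M2,D2,S2,2015-02-01,2015-09-15,3,3,2,1,BW
M4,,S4,2016-02-01,2016-06-01,5,4,2,2,BW
M5,D5,S5,2017-03-01,2017-05-01,4,4,2,2,BW
M5,D5,S5,2017-03-01,2017-07-01,6,4,2,2,BW
M5,D5,S5,2017-03-01,2017-09-01,5,5,3,2,BW
M6,D6,S6,2018-01-10,2018-03-15,8,6,3,3,BW
M6,D6,S6,2018-01-10,2018-05-20,4,4,2,2,BW
M6,D6,S6,2018-01-10,2018-07-25,5,3,1,2,BW
M1,D1,S1,2014-01-05,2014-08-01,4,2,1,1,BW
M4,,S4,2016-02-01,2016-08-01,6,5,3,2,BW
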