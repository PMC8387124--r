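country,period,size
France,2000-2014,61466098
Germany,1998-2015,80892654
Italy,2003-2014,59026383
Spain,1999-2015,44137863
UK,2001-2015,61569167
Czech Republic,1994-2015,10384837
Austria,2002-2016,8420447
Hungary,1996-2015,10055552
Poland,1999-2015,38570112
Slovakia,1996-2014,5407663
Sweden,1997-2015,9215809
Norway,1996-2015,4708433
Denmark,1994-2009,5357073
Finland,1996-2015,5265968
Argentina,2003-2014,40916085
Brazil,2006-2015,196482134
Peru,1999-2015,28032803
Venezuela,1996-2013,26147140
Chile,1997-2015,16109643
Colombia,1997-2013,42606241
Mexico,1998-2012,108139515
Japan,1995-2015,126809629
Australia,1998-2015,20616599
New Zealand,2000-2013,4094611
USA,1999-2010,291683111
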